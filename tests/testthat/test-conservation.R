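test_that("identity_pct basics and direct column-count oracle", {
  set.seed(21)
  x <- random_aa_seq(40)
  expect_equal(identity_pct(x, x), 100)
  # 20 aligned columns, exactly one mismatch, no gaps
  a <- random_aa_seq(20)
  b <- mutate_k(a, 1)
  expect_equal(identity_pct(a, b), 95)
})

test_that("identity is symmetric and flanks do not disturb the core", {
  set.seed(22)
  for (rep in 1:10) {
    a <- random_aa_seq(sample(10:40, 1))
    b <- mutate_k(a, sample(0:5, 1))
    expect_equal(identity_pct(a, b), identity_pct(b, a))
    # identical flanks align to themselves: the gapless column counts predict
    # the flanked identity exactly
    matches <- sum(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
    flank <- random_aa_seq(8)
    expect_equal(identity_pct(paste0(flank, a, flank),
                              paste0(flank, b, flank)),
                 100 * (matches + 16) / (nchar(a) + 16), tolerance = 1e-9)
  }
})

test_that("identity profiles reference the inner LBD at exactly 100", {
  set.seed(23)
  gm <- make_gene_model(two_lbd = TRUE, linker_len = 20, seed = 5)
  prof <- identity_profile(gm$protein, gm$domains)
  expect_identical(prof$label, c("out", "in"))
  expect_equal(prof$identity_pct, c(100, 100))  # identical copies
  # a diverged out copy lands where it was built (60% identity)
  dom <- substr(gm$protein$sequence, gm$domains$start[2] + 1L,
                gm$domains$end[2])
  out60 <- mutate_k(dom, round(0.4 * nchar(dom)))
  seq2 <- paste0(substr(gm$protein$sequence, 1, gm$domains$start[1]),
                 out60,
                 substr(gm$protein$sequence, gm$domains$end[1] + 1L,
                        nchar(gm$protein$sequence)))
  prot2 <- protein_record("p2", seq2)
  ann2 <- gm$domains
  ann2$protein_id <- "p2"
  prof2 <- identity_profile(prot2, ann2)
  expect_gte(prof2$identity_pct[1], 50)
  expect_lte(prof2$identity_pct[1], 70)
  expect_equal(prof2$identity_pct[2], 100)
  # single-LBD protein has nothing to compare
  expect_error(identity_profile(gm$protein, gm$domains[1, ]),
               "nothing to compare")
})

test_that("epitope retention counts identical residues per group", {
  set.seed(24)
  ref <- random_aa_seq(60)
  spec <- data.frame(group = rep(c("F1", "F3"), c(13, 4)),
                     ref_pos_1based = c(1:13, 30:33),
                     contact_type = "polar")
  expect_equal(epitope_retention(ref, ref, spec)$fraction, c(1, 1))
  # 13-position group with exactly 3 substituted positions
  chars <- strsplit(ref, "", fixed = TRUE)[[1]]
  for (p in c(2, 5, 11))
    chars[p] <- setdiff(tandemLBD:::AA_LEVELS, chars[p])[1]
  tgt <- paste(chars, collapse = "")
  ret <- epitope_retention(tgt, ref, spec)
  expect_equal(ret$retained_count[ret$group == "F1"], 10)
  expect_equal(ret$fraction[ret$group == "F1"], 10 / 13, tolerance = 1e-12)
  # all positions deleted -> 0
  tgt2 <- substr(ref, 34, 60)
  ret2 <- epitope_retention(tgt2, ref, spec)
  expect_equal(ret2$fraction[ret2$group == "F1"], 0)
})

test_that("strict retention never exceeds similarity retention", {
  set.seed(25)
  ref <- random_aa_seq(50)
  spec <- data.frame(group = "G", ref_pos_1based = seq(2, 48, by = 3),
                     contact_type = "hydrophobic")
  for (rep in 1:5) {
    tgt <- mutate_k(ref, sample(5:20, 1))
    strict <- epitope_retention(tgt, ref, spec, mode = "strict")
    similar <- epitope_retention(tgt, ref, spec, mode = "similar")
    expect_true(all(strict$retained_count <= similar$retained_count))
  }
})

test_that("epitope specs are validated", {
  ref <- strrep("ACDEF", 10)
  bad <- data.frame(group = "G", ref_pos_1based = c(3, 3),
                    contact_type = "polar")
  expect_error(epitope_retention(ref, ref, bad), "duplicate")
  far <- data.frame(group = "G", ref_pos_1based = 99, contact_type = "polar")
  expect_error(epitope_retention(ref, ref, far), "beyond reference")
  spec_path <- system.file("extdata", "tgfbr2_like_epitope.synthetic.tsv",
                           package = "tandemLBD")
  spec <- read_epitope_spec(spec_path)
  expect_true(all(c("group", "ref_pos_1based", "contact_type") %in%
                    names(spec)))
})
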