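ligand_model <- function(lig_xyz, ca_xyz = matrix(0, 1, 3),
                         lig_element = "C") {
  n <- nrow(lig_xyz); m <- nrow(ca_xyz)
  atoms <- rbind(
    if (n > 0)
      data.frame(record = "HETATM", serial = seq_len(n), name = "C1",
                 altloc = " ", resname = "LIG", chain = "L",
                 resseq = seq_len(n), x = lig_xyz[, 1], y = lig_xyz[, 2],
                 z = lig_xyz[, 3], occupancy = 1, element = lig_element),
    data.frame(record = "ATOM", serial = n + seq_len(m), name = "CA",
               altloc = " ", resname = "GLY", chain = "R", resseq = seq_len(m),
               x = ca_xyz[, 1], y = ca_xyz[, 2], z = ca_xyz[, 3],
               occupancy = 1, element = "C"))
  structure_model(atoms, if (n > 0) "L" else character(0), "R", id = "hand")
}

test_that("hand-placed atoms give exact octant counts", {
  # the 8 corners (+/-1, +/-1, +/-1) -> all octants occupied
  corners <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  prof <- octant_counts(ligand_model(corners), linker_span(1, 1))
  expect_identical(prof$per_residue$octant_count, 8L)
  expect_true(prof$per_residue$embedded)
  # nearest atom at 5.1 A -> count 0
  prof2 <- octant_counts(ligand_model(matrix(c(5.1, 0, 0), 1)),
                         linker_span(1, 1))
  expect_identical(prof2$per_residue$octant_count, 0L)
  expect_false(prof2$per_residue$embedded)
  # radius is inclusive: an atom at exactly 5.0 A counts
  prof3 <- octant_counts(ligand_model(matrix(c(5, 0, 0), 1)),
                         linker_span(1, 1))
  expect_identical(prof3$per_residue$octant_count, 1L)
  # exactly 5 distinct octants at 3 A -> embedded at the threshold boundary
  five <- corners[1:5, ] / sqrt(3) * 3
  prof4 <- octant_counts(ligand_model(five), linker_span(1, 1))
  expect_identical(prof4$per_residue$octant_count, 5L)
  expect_true(prof4$per_residue$embedded)
  # plane tie-break: zero coordinates go to the positive half-space
  plane <- matrix(c(0, 0, 1,  0, 0, -1), 2, 3, byrow = TRUE)
  prof5 <- octant_counts(ligand_model(plane), linker_span(1, 1))
  expect_identical(prof5$per_residue$octant_count, 2L)  # (+,+,+) and (+,+,-)
  # hydrogens are not heavy atoms
  profH <- octant_counts(ligand_model(corners, lig_element = "H"),
                         linker_span(1, 1))
  expect_identical(profH$per_residue$octant_count, 0L)
})

test_that("vectorized counts equal both brute-force oracles on random models", {
  set.seed(61)
  for (rep in 1:20) {
    rs <- random_structure(n_lig = 120, n_res = 10)
    prof <- octant_counts(rs$model, rs$span)
    brute <- octant_counts_brute(rs$model, rs$span)
    expect_identical(prof$per_residue$octant_count, brute$octant_count)
    expect_identical(prof$per_residue$embedded, brute$embedded)
    expect_identical(prof$per_residue$octant_count,
                     octant_string_oracle(rs$model, rs$span))
    # octant count bounds and the embedded definition
    expect_true(all(prof$per_residue$octant_count %in% 0:8))
    expect_identical(prof$per_residue$embedded,
                     prof$per_residue$octant_count >= 5L)
  }
})

test_that("counts are invariant under joint translation and monotone in radius", {
  set.seed(62)
  for (rep in 1:10) {
    rs <- random_structure(n_lig = 100, n_res = 8)
    base <- octant_counts(rs$model, rs$span)
    shifted <- octant_counts(shift_model(rs$model, stats::runif(3, -40, 40)),
                             rs$span)
    expect_identical(shifted$per_residue$octant_count,
                     base$per_residue$octant_count)
    bigger <- octant_counts(rs$model, rs$span, embedding_params(radius = 7))
    expect_true(all(bigger$per_residue$octant_count >=
                      base$per_residue$octant_count))
  }
})

test_that("generator truth labels match the oracle for every generated model", {
  set.seed(63)
  grid <- expand.grid(shape = c("slab", "shell", "two_lobe"),
                      mode = c("threading", "wrapping"),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    spec <- structure_sim_spec(300, grid$shape[i], 15, grid$mode[i],
                               seed = 630 + i)
    fx <- make_linker_structure(spec)
    prof <- octant_counts(fx$model, fx$span)
    expect_identical(prof$per_residue$octant_count, fx$truth$octant_count,
                     info = paste(grid$shape[i], grid$mode[i]))
  }
  # dense slab threading: at least one residue sees all 8 octants
  fx <- make_linker_structure(structure_sim_spec(600, "slab", 20, "threading",
                                                 seed = 64))
  expect_gte(max(fx$truth$octant_count), 8)
  # wrapping at radius 30 around a 20 A shell: nothing embedded
  fx2 <- make_linker_structure(structure_sim_spec(200, "shell", 30, "wrapping",
                                                  shell_radius = 20,
                                                  path_radius = 30, seed = 65))
  expect_identical(sum(fx2$truth$embedded), 0L)
  # zero-atom ligand: all counts zero
  fx3 <- make_linker_structure(structure_sim_spec(0, "slab", 6, "threading",
                                                  seed = 66))
  expect_identical(fx3$truth$octant_count, rep(0L, 6))
  # impossible geometry errors
  expect_error(make_linker_structure(
    structure_sim_spec(100, "shell", 10, "wrapping", shell_radius = 20,
                       path_radius = 15, seed = 67)),
    "impossible geometry")
})

test_that("PDB round trip and chain checks", {
  fx <- make_linker_structure(structure_sim_spec(80, "two_lobe", 10,
                                                 "threading", seed = 68))
  tmp <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(fx$model, tmp)
  back <- read_pdb(tmp)
  expect_identical(nrow(back$atoms), nrow(fx$model$atoms))
  expect_lt(max(abs(back$atoms$x - fx$model$atoms$x)), 1e-3)
  expect_lt(max(abs(back$atoms$z - fx$model$atoms$z)), 1e-3)
  expect_identical(octant_counts(back, fx$span)$per_residue$octant_count,
                   fx$truth$octant_count)
  expect_error(read_pdb(tmp, receptor_chain = "Q"), "chains found")
})

test_that("find_linker matches the core and extends through G/S flanks", {
  core <- "SESVNNDMIVTDNNGAVKFP"
  expect_identical(find_linker(core)$length, 20L)
  span <- find_linker(paste0("MKAA", "GSGS", core, "GS", "AAWK"))
  expect_identical(span$length, 26L)
  expect_identical(c(span$start, span$end), c(5L, 30L))
  expect_error(find_linker("MKTAAA"), "not found")
  expect_error(find_linker(paste0(core, "AAA", core)), "ambiguous")
})

test_that("misplaced models are excluded with a citing log", {
  spec <- structure_sim_spec(200, "two_lobe", 8, "threading",
                             with_domains = TRUE, seed = 69)
  fx <- make_linker_structure(spec)
  fx$model$id <- "docked"
  pspec <- data.frame(lbd = c("out", "in"),
                      rec_start = c(fx$domain_residues$before[1],
                                    fx$domain_residues$after[1]),
                      rec_end = c(fx$domain_residues$before[2],
                                  fx$domain_residues$after[2]),
                      lig_resseq = paste(1:200, collapse = ","))
  res <- filter_misplaced_models(list(fx$model), pspec, max_dist = 8)
  expect_length(res$kept, 1)
  # translate one domain 50 A away
  bad <- fx$model
  bad$id <- "undocked"
  sel <- bad$atoms$chain == "R" &
    bad$atoms$resseq >= fx$domain_residues$after[1] &
    bad$atoms$resseq <= fx$domain_residues$after[2]
  bad$atoms$x[sel] <- bad$atoms$x[sel] + 50
  res2 <- filter_misplaced_models(list(fx$model, bad), pspec, max_dist = 8)
  expect_length(res2$kept, 1)
  log_bad <- res2$log[res2$log$model == "undocked" & !res2$log$kept, ]
  expect_identical(log_bad$lbd, "in")
  expect_gt(log_bad$min_dist, 8)
  # empty input
  expect_length(filter_misplaced_models(list(), pspec)$kept, 0)
})

make_profile <- function(len, rank, n_emb) {
  structure(list(model_id = sprintf("L%d_r%d", len, rank), rank = rank,
                 linker_length = len,
                 per_residue = data.frame(resseq = seq_len(len),
                                          octant_count = 0L,
                                          embedded = rep(FALSE, len)),
                 n_embedded = as.integer(n_emb)),
            class = "embedding_profile")
}

test_that("min_bivalent_linker finds the smallest fully non-threading length", {
  profs <- c(lapply(1:3, function(r) make_profile(20, r, c(3, 2, 4)[r])),
             lapply(1:3, function(r) make_profile(28, r, c(1, 0, 2)[r])),
             lapply(1:3, function(r) make_profile(36, r, 0)),
             lapply(1:3, function(r) make_profile(44, r, 0)))
  expect_identical(min_bivalent_linker(profs, top_n = 3), 36L)
  # all non-embedded -> smallest length present
  all0 <- c(lapply(1:3, function(r) make_profile(12, r, 0)),
            lapply(1:3, function(r) make_profile(30, r, 0)))
  expect_identical(min_bivalent_linker(all0), 12L)
  # no qualifying length -> NA with status
  none <- lapply(1:3, function(r) make_profile(20, r, 1))
  out <- min_bivalent_linker(none)
  expect_true(is.na(out))
  expect_match(attr(out, "status"), "no linker length")
  # under-populated lengths are skipped with a warning
  thin <- c(lapply(1:2, function(r) make_profile(10, r, 0)),
            lapply(1:3, function(r) make_profile(20, r, 0)))
  expect_warning(res <- min_bivalent_linker(thin), "skipped")
  expect_identical(res, 20L)
})

test_that("min_bivalent_linker recovers constructed answers on random series", {
  set.seed(70)
  for (rep in 1:50) {
    lengths <- sort(sample(seq(12, 60, by = 4), 5))
    answer <- sample(lengths, 1)
    profs <- list()
    for (L in lengths) {
      for (r in 1:3) {
        n_emb <- if (L >= answer) 0L else sample(1:5, 1)
        profs[[length(profs) + 1L]] <- make_profile(L, r, n_emb)
      }
    }
    expect_identical(min_bivalent_linker(profs, top_n = 3),
                     as.integer(answer))
  }
})

test_that("species linkers classify against the cutoff inclusively", {
  cls <- compare_to_cutoff(data.frame(species = c("herring", "human_junction",
                                                  "boundary"),
                                      linker_length = c(44, 20, 36)), 36)
  expect_identical(cls$feasible, c(TRUE, FALSE, TRUE))
  expect_error(compare_to_cutoff(data.frame(species = "x",
                                            linker_length = -1), 36),
               "lengths")
})
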