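test_that("spec validation errors name the offending field", {
  expect_error(clade_sim_spec(n_taxa = 1), "n_taxa")
  expect_error(clade_sim_spec(divergence_times = -3), "divergence_times")
  expect_error(clade_sim_spec(r_true = -0.1), "r_true")
  expect_error(clade_sim_spec(seq_length = 0), "seq_length")
  expect_error(clade_sim_spec(gamma_alpha = 0), "gamma_alpha")
  expect_error(clade_sim_spec(dup_taxon = "nope"), "dup_taxon")
  # times that no star tree can produce
  bad <- data.frame(taxon_a = c("t1", "t1", "t1", "t2", "t2", "t3"),
                    taxon_b = c("t2", "t3", "t4", "t3", "t4", "t4"),
                    time_mya = c(10, 100, 100, 100, 100, 100))
  expect_error(clade_sim_spec(n_taxa = 4, divergence_times = bad),
               "star-additive")
  # additive but only with a negative tip age
  neg <- data.frame(taxon_a = c("t1", "t1", "t2"),
                    taxon_b = c("t2", "t3", "t3"),
                    time_mya = c(10, 10, 200))
  expect_error(clade_sim_spec(n_taxa = 3, divergence_times = neg),
               "negative")
})

test_that("zero-rate and zero-divergence limits are exact", {
  sim <- simulate_clade(clade_sim_spec(n_taxa = 4, divergence_times = 80,
                                       r_true = 0, dup_taxon = "t2",
                                       d_dup_true = 0, seq_length = 500,
                                       seed = 7))
  seqs <- vapply(sim$records, `[[`, character(1), "sequence")
  expect_identical(unname(seqs), rep(sim$truth$root, 5))
  expect_identical(sim$records$t2$sequence, sim$records$t2_dup$sequence)
})

test_that("same seed gives byte-identical outputs", {
  spec <- clade_sim_spec(n_taxa = 3, divergence_times = 120, r_true = 0.002,
                         dup_taxon = "t3", d_dup_true = 0.2,
                         seq_length = 400, seed = 99)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_clade(simulate_clade(spec), d1)
  write_clade(simulate_clade(spec), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("simulated distances are unbiased within Monte-Carlo error", {
  # r_true * T = 0.1 at 10,000 sites: mean estimate within +/- 15% over
  # 20 replicates (the generator's own expectation)
  ds <- vapply(1:20, function(i) {
    sim <- simulate_clade(clade_sim_spec(n_taxa = 2, divergence_times = 100,
                                         r_true = 0.001, seq_length = 10000,
                                         gamma_alpha = 1.0, seed = 1000 + i))
    jtt_distance(sim$records$t1$sequence, sim$records$t2$sequence)$d
  }, numeric(1))
  expect_gt(mean(ds), 0.085)
  expect_lt(mean(ds), 0.115)
})

test_that("non-ultrametric star-additive time tables are honoured", {
  times <- data.frame(taxon_a = c("t1", "t1", "t2"),
                      taxon_b = c("t2", "t3", "t3"),
                      time_mya = c(100, 140, 120))   # ages 60, 40, 80
  spec <- clade_sim_spec(n_taxa = 3, divergence_times = times,
                         r_true = 0.001, seq_length = 200, seed = 3)
  expect_equal(unname(spec$tip_ages), c(60, 40, 80))
  ep <- simulate_clade(spec)$truth$expected_paths
  expect_equal(ep$expected_d, 0.001 * times$time_mya)
})

test_that("gene-model fixtures translate consistently", {
  for (two in c(TRUE, FALSE)) {
    gm <- make_gene_model(two_lbd = two, linker_len = 44, seed = 11)
    expect_identical(translate_gene_model(gm), gm$protein$sequence)
    if (two) {
      expect_identical(gm$linker_len, 44L)
      expect_identical(nrow(gm$domains), 2L)
    } else {
      expect_true(is.na(gm$linker_len))
      expect_identical(nrow(gm$domains), 1L)
      expect_true(is.na(linker_length_from_domains(gm$domains)))
    }
  }
  # adjacent domains when linker_len = 0
  gm0 <- make_gene_model(two_lbd = TRUE, linker_len = 0, seed = 12)
  expect_identical(linker_length_from_domains(gm0$domains)$linker_length, 0L)
})
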