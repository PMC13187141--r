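test_that("discrete gamma categories are normalized", {
  for (alpha in c(0.3, 1.0, 5)) {
    gm <- gamma_model(alpha, 4)
    expect_equal(sum(gm$weights), 1)
    expect_equal(sum(gm$rates * gm$weights), 1)
    expect_true(all(diff(gm$rates) > 0))
  }
  expect_equal(gamma_model(Inf, 4)$rates, rep(1, 4))
  expect_error(gamma_model(-1), "alpha")
})

test_that("jtt_distance: identical, symmetric, saturated", {
  set.seed(31)
  x <- random_aa_seq(300)
  expect_equal(jtt_distance(x, x)$d, 0, tolerance = 1e-6)
  y <- mutate_k(x, 60)
  expect_equal(jtt_distance(x, y)$d, jtt_distance(y, x)$d)
  # sequences differing at every site hit the d_max boundary
  a <- strrep("A", 200)
  w <- strrep("W", 200)
  est <- jtt_distance(a, w)
  expect_true(est$saturated)
  expect_equal(est$d, 10)
})

test_that("small-divergence limit: d is close to the p-distance", {
  set.seed(32)
  for (p_sub in c(1, 4)) {   # p = 0.005, 0.02 at 200 sites
    x <- random_aa_seq(200)
    y <- mutate_k(x, p_sub)
    p <- p_sub / 200
    expect_lte(abs(jtt_distance(x, y)$d - p), 0.01)
  }
})

test_that("d is monotone in the p-distance (20-step nested ladder)", {
  set.seed(33)
  x <- random_aa_seq(500)
  xc <- strsplit(x, "", fixed = TRUE)[[1]]
  untouched <- seq_along(xc)
  yc <- xc
  ds <- numeric(20)
  for (step in 1:20) {               # add 5 fresh substitutions per step
    pos <- sample(untouched, 5)
    untouched <- setdiff(untouched, pos)
    for (p in pos) yc[p] <- sample(setdiff(tandemLBD:::AA_LEVELS, xc[p]), 1)
    ds[step] <- jtt_distance(x, paste(yc, collapse = ""))$d
  }
  expect_equal(cor(ds, 1:20, method = "spearman"), 1)
})

test_that("optimizer agrees with the grid-search likelihood oracle", {
  set.seed(34)
  grid <- seq(0, 2, length.out = 401)
  for (k in c(10, 60, 150)) {
    x <- random_aa_seq(400)
    y <- mutate_k(x, k)
    gm <- gamma_model(1.0, 4)
    d_opt <- jtt_distance(x, y, gm)$d
    d_grid <- grid_distance_oracle(x, y, gm, grid)
    expect_lte(abs(d_opt - d_grid), grid[2] - grid[1])
  }
})

test_that("likelihood matches the independent matrix-exponential oracle", {
  set.seed(35)
  x <- random_aa_seq(60)
  y <- mutate_k(x, 12)
  gm <- gamma_model(1.0, 4)
  for (d in c(0.05, 0.3, 1.2)) {
    expect_equal(tandemLBD:::loglik_counts(d, tandemLBD:::pair_counts(x, y), gm),
                 loglik_oracle(x, y, d, gm), tolerance = 1e-8)
  }
})

test_that("bootstrap variance: zero for identical pairs, seed-reproducible", {
  set.seed(36)
  x <- random_aa_seq(200)
  expect_identical(bootstrap_variance(x, x, n_boot = 50)$variance, 0)
  y <- mutate_k(x, 30)
  v1 <- bootstrap_variance(x, y, n_boot = 100, seed = 9)$variance
  v2 <- bootstrap_variance(x, y, n_boot = 100, seed = 9)$variance
  expect_identical(v1, v2)
  expect_gt(v1, 0)
})

test_that("bootstrap variance shrinks with sequence length", {
  # Monte-Carlo consistency, scaled down: medians over 5 simulated pairs
  vs <- sapply(1:5, function(i) {
    long <- simulate_clade(clade_sim_spec(n_taxa = 2, divergence_times = 100,
                                          r_true = 0.001, seq_length = 5000,
                                          seed = 400 + i))
    short <- simulate_clade(clade_sim_spec(n_taxa = 2, divergence_times = 100,
                                           r_true = 0.001, seq_length = 300,
                                           seed = 500 + i))
    c(long = bootstrap_variance(long$records$t1$sequence,
                                long$records$t2$sequence,
                                n_boot = 100, seed = i)$variance,
      short = bootstrap_variance(short$records$t1$sequence,
                                 short$records$t2$sequence,
                                 n_boot = 100, seed = i)$variance)
  })
  expect_lt(median(vs["long", ]), median(vs["short", ]))
})

test_that("fit_clock recovers exact noise-free slopes", {
  times <- data.frame(taxon_a = letters[1:5], taxon_b = LETTERS[1:5],
                      time_mya = c(10, 50, 100, 150, 230))
  est <- data.frame(taxon_a = letters[1:5], taxon_b = LETTERS[1:5],
                    d = 0.002 * times$time_mya, variance = 1e-6)
  fit <- fit_clock(est, times)
  expect_lt(abs(fit$r - 0.002), 1e-12)
  # single pair through the origin
  fit1 <- fit_clock(est[2, ], times)
  expect_equal(fit1$r, est$d[2] / 50)
  # missing time entry names the pair
  est_bad <- est
  est_bad$taxon_a[1] <- "zz"
  expect_error(fit_clock(est_bad, times), "zz")
  # zero variances get the largest finite weight, not Inf
  est$variance[1] <- 0
  expect_silent(fit_clock(est, times))
})

test_that("duplication rates follow their definition", {
  times <- data.frame(taxon_a = "a", taxon_b = "b", time_mya = 100)
  est <- data.frame(taxon_a = "a", taxon_b = "b", d = 0.1, variance = 1e-5)
  fit <- fit_clock(est, times)   # r = 0.001
  expect_equal(duplication_rate(0, fit)$r_dup, 0)
  rd <- duplication_rate(0.30, fit)
  expect_equal(rd$r_dup, 300)
  expect_equal(duplication_rate(0.30, fit, t_dup = 100)$relative_rate, 3)
  fit0 <- fit
  fit0$r <- 0
  expect_error(duplication_rate(0.1, fit0), "must be > 0")
})
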