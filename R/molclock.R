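# JTT+Gamma pairwise ML distances, site-bootstrap variances, molecular-clock
# weighted regression against divergence times, and duplication-specific
# rates.
#
# Model: per site, P(b | a, d) = sum_k w_k P_JTT(a -> b | d * r_k) with r_k a
# k-category discrete gamma (median category rates, renormalized to mean 1).
# Columns where either sequence carries '-' or 'X' are dropped (pairwise
# deletion). d maximizes the log-likelihood by bounded scalar optimization.

#' Discrete-gamma model of across-site rate variation
#'
#' Equal-weight categories with median category rates
#' `qgamma((2k - 1) / (2K), alpha, alpha)`, renormalized so the mean category
#' rate is exactly 1. `alpha = Inf` disables rate variation (single category).
#'
#' @param alpha gamma shape (> 0; default 1.0).
#' @param k number of categories (default 4).
#' @return list `gamma_model` with `alpha`, `k`, `rates`, `weights`.
#' @export
gamma_model <- function(alpha = 1.0, k = 4L) {
  assert_scalar_num(alpha, "alpha", lower = 0, strict = TRUE, allow_inf = TRUE)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k))
    abort_field("k", "must be a positive integer")
  k <- as.integer(k)
  if (is.infinite(alpha) || k == 1L) {
    rates <- rep(1, k)
  } else {
    rates <- stats::qgamma((2 * seq_len(k) - 1) / (2 * k), shape = alpha,
                           rate = alpha)
    rates <- rates * k / sum(rates)
  }
  structure(list(alpha = alpha, k = k, rates = rates, weights = rep(1 / k, k)),
            class = "gamma_model")
}

# 20x20 site-pattern count matrix after pairwise deletion. Accepts aligned
# (equal-length, possibly gapped) strings; unaligned inputs of equal length
# are treated as already aligned, otherwise they are globally aligned first.
pair_counts <- function(a, b, params = align_params()) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) {
    al <- align_global(gsub("-", "", a, fixed = TRUE),
                       gsub("-", "", b, fixed = TRUE), params)
    a <- al$aligned_a; b <- al$aligned_b
  }
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  ia <- match(ca, AA_LEVELS); ib <- match(cb, AA_LEVELS)
  use <- !is.na(ia) & !is.na(ib)      # pairwise deletion of gaps/X/unknown
  N <- matrix(0, 20, 20, dimnames = list(AA_LEVELS, AA_LEVELS))
  if (any(use)) {
    tab <- table(factor(ia[use], levels = 1:20), factor(ib[use], levels = 1:20))
    N[] <- as.numeric(tab)
  }
  N
}

# Mixture matrix M_ij(d) = pi_i * sum_k w_k P_ij(d * r_k); log-likelihood of a
# count matrix is sum(N * log M).
mixture_matrix <- function(d, gamma) {
  m <- jtt_model()
  M <- matrix(0, 20, 20)
  for (k in seq_len(gamma$k)) {
    P <- m$vectors %*% (exp(m$values * (d * gamma$rates[k])) * m$inv)
    M <- M + gamma$weights[k] * P
  }
  M[M < 1e-300] <- 1e-300
  M * m$pi
}

loglik_counts <- function(d, N, gamma) sum(N * log(mixture_matrix(d, gamma)))

#' Pairwise JTT+Gamma maximum-likelihood distance
#'
#' @param a,b sequences; equal-length inputs are taken as an aligned pair
#'   (gaps allowed), otherwise they are globally aligned first.
#' @param gamma a [gamma_model()] (default shape 1.0, k = 4).
#' @param d_max optimizer upper bound (substitutions/site).
#' @param tol optimizer tolerance.
#' @param params alignment parameters used when alignment is needed.
#' @return list `distance_estimate`: `d`, `n_sites`, `loglik`, `saturated`
#'   (TRUE when the optimum sits at the `d_max` boundary), and the pair
#'   count matrix in `counts`.
#' @export
jtt_distance <- function(a, b, gamma = gamma_model(), d_max = 10,
                         tol = 1e-6, params = align_params()) {
  N <- pair_counts(a, b, params)
  jtt_distance_counts(N, gamma, d_max, tol)
}

jtt_distance_counts <- function(N, gamma = gamma_model(), d_max = 10,
                                tol = 1e-6) {
  n_sites <- sum(N)
  if (n_sites < 1)
    stop("no usable columns after pairwise deletion", call. = FALSE)
  if (sum(N) == sum(diag(N))) {      # identical over used sites
    return(structure(list(d = 0, n_sites = n_sites,
                          loglik = loglik_counts(0, N, gamma),
                          saturated = FALSE, counts = N),
                     class = "distance_estimate"))
  }
  opt <- stats::optimize(loglik_counts, c(0, d_max), N = N, gamma = gamma,
                         maximum = TRUE, tol = tol)
  d <- opt$maximum
  saturated <- d > d_max - 10 * tol ||
    loglik_counts(d_max, N, gamma) >= opt$objective
  if (saturated) d <- d_max
  structure(list(d = d, n_sites = n_sites, loglik = opt$objective,
                 saturated = saturated, counts = N),
            class = "distance_estimate")
}

#' @export
print.distance_estimate <- function(x, ...) {
  cat(sprintf("<distance_estimate> d=%.6f n_sites=%d%s%s\n", x$d,
              as.integer(x$n_sites),
              if (!is.null(x$variance)) sprintf(" var=%.3g", x$variance) else "",
              if (isTRUE(x$saturated)) " [saturated]" else ""))
  invisible(x)
}

#' Site-bootstrap variance of the JTT+Gamma distance
#'
#' Resamples alignment columns (multinomially over the observed site
#' patterns) and re-estimates the distance; returns the variance across
#' replicates. Identical sequences have variance 0 by construction.
#'
#' @inheritParams jtt_distance
#' @param n_boot number of replicates (default 1000).
#' @param seed RNG seed (reproducible; `NULL` uses the current stream).
#' @return list: `variance`, `n_boot`, plus the point estimate under `est`.
#' @export
bootstrap_variance <- function(a, b, gamma = gamma_model(), n_boot = 1000L,
                               seed = NULL, d_max = 10, tol = 1e-6,
                               params = align_params()) {
  N <- pair_counts(a, b, params)
  est <- jtt_distance_counts(N, gamma, d_max, tol)
  if (est$d == 0 && sum(N) == sum(diag(N)))
    return(list(variance = 0, n_boot = as.integer(n_boot), est = est))
  n_sites <- sum(N)
  prob <- as.vector(N) / n_sites
  reps <- with_seed(seed, {
    draws <- stats::rmultinom(n_boot, size = n_sites, prob = prob)
    vapply(seq_len(n_boot), function(r) {
      Nb <- matrix(draws[, r], 20, 20)
      jtt_distance_counts(Nb, gamma, d_max, tol)$d
    }, numeric(1))
  })
  list(variance = stats::var(reps), n_boot = as.integer(n_boot), est = est)
}

#' Pairwise distances with bootstrap variances for a set of domain records
#'
#' @param records named list of [protein_record()]s (aligned or unaligned).
#' @param gamma a [gamma_model()].
#' @param n_boot bootstrap replicates per pair (0 disables variances).
#' @param seed master seed; each pair gets a derived substream.
#' @inheritParams jtt_distance
#' @return data.frame: `taxon_a`, `taxon_b`, `d`, `variance`, `n_sites`,
#'   `saturated`.
#' @export
pairwise_distances <- function(records, gamma = gamma_model(), n_boot = 1000L,
                               seed = NULL, d_max = 10, tol = 1e-6,
                               params = align_params()) {
  records <- as_records(records)
  ids <- vapply(records, `[[`, character(1), "id")
  n <- length(records)
  if (n < 2) abort_field("records", "need at least two records")
  rows <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sub_seed <- if (is.null(seed)) NULL else
      substream_seed(seed, paste(ids[i], ids[j], sep = "|"))
    if (n_boot > 0) {
      bv <- bootstrap_variance(records[[i]]$sequence, records[[j]]$sequence,
                               gamma, n_boot, sub_seed, d_max, tol, params)
      est <- bv$est; v <- bv$variance
    } else {
      est <- jtt_distance(records[[i]]$sequence, records[[j]]$sequence,
                          gamma, d_max, tol, params)
      v <- NA_real_
    }
    rows[[length(rows) + 1L]] <-
      data.frame(taxon_a = ids[i], taxon_b = ids[j], d = est$d, variance = v,
                 n_sites = est$n_sites, saturated = est$saturated)
  }
  do.call(rbind, rows)
}

#' Read a pairwise divergence-time table
#'
#' TSV with header `taxon_a  taxon_b  time_mya` (times in Myr, e.g. exported
#' from a divergence-time database).
#' @param path TSV file.
#' @export
read_divergence_table <- function(path) {
  df <- read_tsv(path)
  need <- c("taxon_a", "taxon_b", "time_mya")
  if (!all(need %in% names(df)))
    abort_field("divergence table", paste("missing column(s):",
                paste(setdiff(need, names(df)), collapse = ", ")))
  if (any(df$time_mya <= 0))
    abort_field("divergence table", "all times must be > 0")
  df
}

lookup_time <- function(times, a, b) {
  hit <- (times$taxon_a == a & times$taxon_b == b) |
    (times$taxon_a == b & times$taxon_b == a)
  if (!any(hit)) stop(sprintf("no divergence time for pair %s / %s", a, b),
                      call. = FALSE)
  times$time_mya[which(hit)[1]]
}

#' Fit a molecular clock by weighted regression of distance on time
#'
#' Weighted least squares of pairwise distance `d` on divergence time `T`
#' (Myr). The slope is the clade rate `r` in substitutions/site/Myr on the
#' pairwise-path convention (`d = r * T`). By default the fit is through the
#' origin (a clock forces `d -> 0` as `T -> 0`); inverse-bootstrap-variance
#' weights are the default, with zero variances mapped to the largest finite
#' weight present.
#'
#' @param estimates data.frame from [pairwise_distances()] (columns
#'   `taxon_a`, `taxon_b`, `d`, and `variance` for inverse-variance weights).
#' @param times divergence table (`taxon_a`, `taxon_b`, `time_mya`).
#' @param weighting `"inverse-variance"` or `"uniform"`.
#' @param through_origin force a zero intercept (default TRUE).
#' @param clade clade identifier stored in the result.
#' @return list `clock_fit`: `clade`, `r`, `se_r`, `intercept`, `weighting`,
#'   `n_pairs`, `residuals`, `fit` (the underlying `lm`).
#' @export
fit_clock <- function(estimates, times, weighting = c("inverse-variance",
                                                      "uniform"),
                      through_origin = TRUE, clade = "clade") {
  weighting <- match.arg(weighting)
  assert_flag(through_origin, "through_origin")
  n <- nrow(estimates)
  if (n < 1) abort_field("estimates", "need at least one pair")
  if (!through_origin && n < 2)
    abort_field("estimates", "free-intercept fit needs >= 2 pairs")
  T_ <- vapply(seq_len(n), function(i)
    lookup_time(times, estimates$taxon_a[i], estimates$taxon_b[i]),
    numeric(1))
  d <- estimates$d
  if (weighting == "inverse-variance") {
    v <- estimates$variance
    if (is.null(v) || all(!is.finite(v)))
      abort_field("estimates", "no variances available for weighting")
    w <- 1 / v
    if (any(!is.finite(w))) {
      finite <- w[is.finite(w)]
      w[!is.finite(w)] <- if (length(finite)) max(finite) else 1
    }
  } else w <- rep(1, n)
  df_fit <- data.frame(d = d, T_ = T_)
  fit <- if (through_origin) stats::lm(d ~ 0 + T_, data = df_fit, weights = w)
         else stats::lm(d ~ T_, data = df_fit, weights = w)
  co <- summary(fit)$coefficients
  slope_row <- if (through_origin) 1L else 2L
  r <- unname(co[slope_row, 1])
  se_naive <- unname(co[slope_row, 2])
  if (!is.finite(se_naive)) se_naive <- NA_real_
  # Pairwise distances on a star topology are NOT independent: pairs sharing
  # a taxon share that lineage's estimation error, and the ordinary
  # regression SE undercovers badly. se_r therefore propagates per-lineage
  # variance components (Var(d_ab) = v_a + v_b, solved from the bootstrap
  # pair variances) through the slope's linear form; the naive SE is kept as
  # a diagnostic in se_naive.
  se <- se_cov_aware(estimates, T_, w, through_origin)
  if (!is.finite(se)) se <- se_naive
  structure(list(clade = clade, r = r, se_r = se, se_naive = se_naive,
                 intercept = if (through_origin) 0 else unname(co[1, 1]),
                 weighting = weighting, n_pairs = n,
                 residuals = unname(stats::residuals(fit)), fit = fit),
            class = "clock_fit")
}

# correlation-aware slope variance: slope = sum(c_i d_i) with
# c_i = w_i T_i / sum(w T^2) (through-origin case; the free-intercept slope
# uses the centred form). Cov(d_i, d_j) = sum over shared taxa of v_t, with
# v solved from the pair-variance decomposition Var(d_ab) = v_a + v_b.
se_cov_aware <- function(estimates, T_, w, through_origin) {
  v_pair <- estimates$variance
  if (is.null(v_pair) || any(!is.finite(v_pair))) return(NA_real_)
  taxa <- unique(c(estimates$taxon_a, estimates$taxon_b))
  n <- nrow(estimates)
  A <- matrix(0, n, length(taxa))
  A[cbind(seq_len(n), match(estimates$taxon_a, taxa))] <- 1
  A[cbind(seq_len(n), match(estimates$taxon_b, taxa))] <- 1
  sv <- svd(A)
  keep <- sv$d > max(sv$d) * 1e-10
  v <- as.numeric(sv$v[, keep, drop = FALSE] %*%
                    ((t(sv$u[, keep, drop = FALSE]) %*% v_pair) / sv$d[keep]))
  v <- pmax(v, 0)
  V <- A %*% (v * t(A))        # Cov(d_i, d_j) = sum_t v_t [t in both pairs]
  diag(V) <- pmax(v_pair, 0)   # exact bootstrap variance on the diagonal
  if (through_origin) {
    cc <- w * T_ / sum(w * T_^2)
  } else {
    Tw <- sum(w * T_) / sum(w)
    cc <- w * (T_ - Tw) / sum(w * (T_ - Tw)^2)
    if (!all(is.finite(cc))) return(NA_real_)
  }
  sqrt(drop(t(cc) %*% V %*% cc))
}

#' @export
print.clock_fit <- function(x, ...) {
  cat(sprintf("<clock_fit> %s: r=%.6g subst/site/Myr (se %.3g), %d pairs, %s\n",
              x$clade, x$r, x$se_r, x$n_pairs, x$weighting))
  invisible(x)
}

#' Duplication-specific rate
#'
#' The distance between the two LBD copies of a focal protein divided by the
#' clade clock rate (`r_dup = d_dup / r`; note this literal quantity has
#' units of Myr). When a duplication age `t_dup` is supplied, the
#' dimensionless relative rate `d_dup / (r * t_dup)` is also returned: 1
#' means the copies diverged at the clade's clock rate, 5 means five-fold
#' acceleration.
#'
#' @param d_dup a `distance_estimate` (or bare number) for the copy pair.
#' @param clock a `clock_fit` with `r > 0`.
#' @param t_dup optional duplication age (Myr).
#' @param focal focal protein identifier.
#' @return list `duplication_rate`: `focal`, `d_dup`, `r_clade`, `r_dup`,
#'   `relative_rate` (NA without `t_dup`).
#' @export
duplication_rate <- function(d_dup, clock, t_dup = NULL, focal = "focal") {
  d <- if (inherits(d_dup, "distance_estimate")) d_dup$d else d_dup
  assert_scalar_num(d, "d_dup", lower = 0)
  if (!inherits(clock, "clock_fit")) abort_field("clock", "must be a clock_fit")
  if (!is.finite(clock$r) || clock$r <= 0)
    stop("duplication rate undefined: clade clock rate must be > 0",
         call. = FALSE)
  rel <- NA_real_
  if (!is.null(t_dup)) {
    assert_scalar_num(t_dup, "t_dup", lower = 0, strict = TRUE)
    rel <- d / (clock$r * t_dup)
  }
  structure(list(focal = focal, d_dup = d, r_clade = clock$r,
                 r_dup = d / clock$r, relative_rate = rel),
            class = "duplication_rate")
}

#' @export
print.duplication_rate <- function(x, ...) {
  cat(sprintf("<duplication_rate> %s: d_dup=%.4f r_clade=%.3g r_dup=%.4g%s\n",
              x$focal, x$d_dup, x$r_clade, x$r_dup,
              if (is.na(x$relative_rate)) "" else
                sprintf(" relative=%.3g", x$relative_rate)))
  invisible(x)
}
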