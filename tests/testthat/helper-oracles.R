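# Independent brute-force oracles. These deliberately share no code with the
# implementation: alignment scores come from a plain memoized recursion over
# (i, j, previous-column-state); transition probabilities from a
# scaling-and-squaring matrix exponential; octant counts from explicit
# per-atom loops (octant_counts_brute in the package, which is itself
# loop-based and is additionally cross-checked here against a third,
# string-based classifier).

# --- affine-gap alignment score oracle (recursion, suffix formulation) ------

align_score_oracle <- function(a, b, mode = "global",
                               sub = tandemLBD:::blosum62(),
                               go = 10, ge = 1) {
  ac <- strsplit(a, "", fixed = TRUE)[[1]]
  bc <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(ac); m <- length(bc)
  memo <- array(NA_real_, dim = c(n + 1L, m + 1L, 3L))
  g <- function(i, j, prev) {
    if (i > n && j > m) return(0)
    if (!is.na(memo[i, j, prev])) return(memo[i, j, prev])
    best <- -Inf
    if (i <= n && j <= m)
      best <- max(best, sub[ac[i], bc[j]] + g(i + 1L, j + 1L, 1L))
    if (i <= n)
      best <- max(best, -(if (prev == 2L) ge else go) + g(i + 1L, j, 2L))
    if (j <= m)
      best <- max(best, -(if (prev == 3L) ge else go) + g(i, j + 1L, 3L))
    memo[i, j, prev] <<- best
    best
  }
  if (mode == "global") return(g(1L, 1L, 1L))
  # local: alignment may start and stop anywhere (score floor 0)
  gl <- function(i, j, prev) {
    if (i > n && j > m) return(0)
    if (!is.na(memo[i, j, prev])) return(memo[i, j, prev])
    best <- 0
    if (i <= n && j <= m)
      best <- max(best, sub[ac[i], bc[j]] + gl(i + 1L, j + 1L, 1L))
    if (i <= n)
      best <- max(best, -(if (prev == 2L) ge else go) + gl(i + 1L, j, 2L))
    if (j <= m)
      best <- max(best, -(if (prev == 3L) ge else go) + gl(i, j + 1L, 3L))
    memo[i, j, prev] <<- best
    best
  }
  best <- 0
  for (i in seq_len(n + 1L)) for (j in seq_len(m + 1L))
    best <- max(best, gl(i, j, 1L))
  best
}

random_aa_seq <- function(n) paste(sample(tandemLBD:::AA_LEVELS, n,
                                          replace = TRUE), collapse = "")

# --- matrix exponential oracle for JTT transition probabilities -------------

expm_oracle <- function(A) {
  nrm <- max(abs(A))
  k <- max(0L, ceiling(log2(max(1, nrm))))
  B <- A / 2^k
  P <- diag(nrow(A))
  term <- diag(nrow(A))
  for (i in 1:20) {
    term <- term %*% B / i
    P <- P + term
  }
  for (i in seq_len(k)) P <- P %*% P
  P
}

# site-wise JTT+gamma log-likelihood oracle (no count matrices)
loglik_oracle <- function(a, b, d, gamma) {
  m <- jtt_model()
  Ps <- lapply(gamma$rates, function(r) expm_oracle(m$Q * d * r))
  ca <- match(strsplit(a, "", fixed = TRUE)[[1]], tandemLBD:::AA_LEVELS)
  cb <- match(strsplit(b, "", fixed = TRUE)[[1]], tandemLBD:::AA_LEVELS)
  use <- !is.na(ca) & !is.na(cb)
  sum(vapply(which(use), function(s) {
    lik <- 0
    for (k in seq_along(Ps))
      lik <- lik + gamma$weights[k] * m$pi[ca[s]] * Ps[[k]][ca[s], cb[s]]
    log(lik)
  }, numeric(1)))
}

# grid-search distance oracle: arg max of the site-wise likelihood on a grid
grid_distance_oracle <- function(a, b, gamma, grid = seq(0, 2, length.out = 201)) {
  ll <- vapply(grid, function(d)
    tandemLBD:::loglik_counts(d, tandemLBD:::pair_counts(a, b), gamma),
    numeric(1))
  grid[which.max(ll)]
}

# --- third octant classifier (string keyed, set based) ----------------------

octant_string_oracle <- function(model, span, params = embedding_params()) {
  lig <- tandemLBD:::ligand_heavy_atoms(model)
  ca <- tandemLBD:::receptor_ca(model)
  ca <- ca[ca$resseq >= span$start & ca$resseq <= span$end, , drop = FALSE]
  counts <- integer(nrow(ca))
  for (i in seq_len(nrow(ca))) {
    keys <- character(0)
    for (j in seq_len(nrow(lig))) {
      v <- c(lig$x[j] - ca$x[i], lig$y[j] - ca$y[i], lig$z[j] - ca$z[i])
      if (sqrt(sum(v^2)) > params$radius) next
      keys <- c(keys, paste(ifelse(v < 0, "-", "+"), collapse = ""))
    }
    counts[i] <- length(unique(keys))
  }
  counts
}

# random structure model: ligand point cloud + random linker path
random_structure <- function(n_lig = 150, n_res = 12) {
  lig <- matrix(stats::runif(3 * n_lig, -8, 8), ncol = 3)
  start <- stats::runif(3, -10, 10)
  dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
  path <- t(sapply(seq_len(n_res) - 1, function(i) start + i * 3.8 * dir))
  atoms <- rbind(
    data.frame(record = "HETATM", serial = seq_len(n_lig), name = "C1",
               altloc = " ", resname = "LIG", chain = "L",
               resseq = seq_len(n_lig), x = lig[, 1], y = lig[, 2],
               z = lig[, 3], occupancy = 1, element = "C"),
    data.frame(record = "ATOM", serial = n_lig + seq_len(n_res), name = "CA",
               altloc = " ", resname = "GLY", chain = "R",
               resseq = seq_len(n_res), x = path[, 1], y = path[, 2],
               z = path[, 3], occupancy = 1, element = "C"))
  list(model = structure_model(atoms, "L", "R", id = "random"),
       span = linker_span(1, n_res))
}

# mutate a sequence at exactly k positions (always to a different residue)
mutate_k <- function(seq, k) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample(seq_along(chars), k)
  for (p in pos) {
    chars[p] <- sample(setdiff(tandemLBD:::AA_LEVELS, chars[p]), 1)
  }
  paste(chars, collapse = "")
}
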