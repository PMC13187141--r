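# Pairwise alignment: Gotoh affine-gap dynamic programming.
#
# Conventions fixed by contract (and relied on elsewhere):
#   * scores are maximized under a substitution matrix (default BLOSUM62);
#   * a gap run of length L costs gap_open + (L - 1) * gap_extend;
#   * ties are broken deterministically: diagonal, then up (gap in `b`),
#     then left (gap in `a`);
#   * local alignments break best-cell ties toward the smallest (i, j).

#' Alignment parameters
#'
#' @param submat substitution matrix (rownames/colnames = residues). Default
#'   BLOSUM62.
#' @param gap_open cost of the first residue of a gap (positive number).
#' @param gap_extend cost of each further gap residue.
#' @export
align_params <- function(submat = NULL, gap_open = 10, gap_extend = 1) {
  if (is.null(submat)) submat <- blosum62()
  assert_scalar_num(gap_open, "gap_open", lower = 0)
  assert_scalar_num(gap_extend, "gap_extend", lower = 0)
  list(submat = submat, gap_open = gap_open, gap_extend = gap_extend)
}

# Core Gotoh DP. States: 1 = M (diagonal), 2 = Ix (up, gap in b),
# 3 = Iy (left, gap in a).
gotoh <- function(a, b, params, mode = c("global", "local")) {
  mode <- match.arg(mode)
  ac <- strsplit(a, "", fixed = TRUE)[[1]]
  bc <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(ac); m <- length(bc)
  sub <- params$submat
  ai <- match(ac, rownames(sub)); bi <- match(bc, colnames(sub))
  if (anyNA(ai)) abort_field("a", "residue absent from substitution matrix")
  if (anyNA(bi)) abort_field("b", "residue absent from substitution matrix")
  go <- params$gap_open; ge <- params$gap_extend
  NEG <- -1e18

  M <- matrix(NEG, n + 1L, m + 1L)
  Ix <- matrix(NEG, n + 1L, m + 1L)
  Iy <- matrix(NEG, n + 1L, m + 1L)
  # pointer matrices: for M, predecessor state of the diagonal step;
  # for Ix/Iy, 1 = opened from M, 0 = extended.
  pM <- matrix(0L, n + 1L, m + 1L)
  pIx <- matrix(0L, n + 1L, m + 1L)
  pIy <- matrix(0L, n + 1L, m + 1L)

  M[1, 1] <- 0
  if (mode == "global") {
    if (n > 0) Ix[2:(n + 1), 1] <- -go - (seq_len(n) - 1) * ge
    if (m > 0) Iy[1, 2:(m + 1)] <- -go - (seq_len(m) - 1) * ge
  } else {
    M[, 1] <- 0; M[1, ] <- 0
  }

  best <- c(score = if (mode == "local") 0 else NEG, i = 0L, j = 0L, st = 1L)
  for (i in seq_len(n)) {
    srow <- sub[ai[i], ]
    for (j in seq_len(m)) {
      # M: diagonal step, predecessor preference M > Ix > Iy
      dm <- M[i, j]; dx <- Ix[i, j]; dy <- Iy[i, j]
      pred <- if (dm >= dx && dm >= dy) 1L else if (dx >= dy) 2L else 3L
      pv <- c(dm, dx, dy)[pred]
      mv <- pv + srow[bi[j]]
      if (mode == "local" && mv < 0) { mv <- 0; pred <- 0L }
      M[i + 1L, j + 1L] <- mv
      pM[i + 1L, j + 1L] <- pred
      # Ix: consume a_i (up)
      fromM <- M[i, j + 1L] - go
      ext <- Ix[i, j + 1L] - ge
      if (fromM >= ext) { Ix[i + 1L, j + 1L] <- fromM; pIx[i + 1L, j + 1L] <- 1L
      } else Ix[i + 1L, j + 1L] <- ext
      # Iy: consume b_j (left)
      fromM <- M[i + 1L, j] - go
      ext <- Iy[i + 1L, j] - ge
      if (fromM >= ext) { Iy[i + 1L, j + 1L] <- fromM; pIy[i + 1L, j + 1L] <- 1L
      } else Iy[i + 1L, j + 1L] <- ext
      if (mode == "local" && M[i + 1L, j + 1L] > best["score"]) {
        best <- c(score = M[i + 1L, j + 1L], i = i, j = j, st = 1L)
      }
    }
  }

  if (mode == "global") {
    vals <- c(M[n + 1L, m + 1L], Ix[n + 1L, m + 1L], Iy[n + 1L, m + 1L])
    st <- which(vals == max(vals))[1]
    best <- c(score = vals[st], i = n, j = m, st = st)
  }

  # traceback
  i <- as.integer(best["i"]); j <- as.integer(best["j"])
  st <- as.integer(best["st"])
  end_a <- i; end_b <- j
  ra <- character(0); rb <- character(0)
  repeat {
    if (mode == "global") { if (i == 0L && j == 0L) break
    } else if (st == 1L && M[i + 1L, j + 1L] == 0) break
    if (st == 1L) {
      ra <- c(ac[i], ra); rb <- c(bc[j], rb)
      nxt <- pM[i + 1L, j + 1L]
      i <- i - 1L; j <- j - 1L
      if (mode == "local" && nxt == 0L) { st <- 1L; break }
      st <- nxt
      if (mode == "global" && i == 0L && j == 0L) break
    } else if (st == 2L) {
      ra <- c(ac[i], ra); rb <- c("-", rb)
      opened <- pIx[i + 1L, j + 1L] == 1L
      i <- i - 1L
      if (opened) st <- 1L
    } else {
      ra <- c("-", ra); rb <- c(bc[j], rb)
      opened <- pIy[i + 1L, j + 1L] == 1L
      j <- j - 1L
      if (opened) st <- 1L
    }
  }
  list(score = unname(best["score"]),
       aligned_a = paste(ra, collapse = ""),
       aligned_b = paste(rb, collapse = ""),
       start_a = i + 1L, end_a = end_a,
       start_b = j + 1L, end_b = end_b)
}

#' Global pairwise alignment (Needleman-Wunsch, affine gaps)
#'
#' @param a,b amino-acid sequences (strings; gaps not allowed).
#' @param params see [align_params()].
#' @return An `alignment_result`: equal-length gapped strings `aligned_a`,
#'   `aligned_b`, the optimal `score`, and the parameters used.
#' @export
align_global <- function(a, b, params = align_params()) {
  a <- validate_aa(a, "a"); b <- validate_aa(b, "b")
  res <- gotoh(a, b, params, "global")
  structure(list(aligned_a = res$aligned_a, aligned_b = res$aligned_b,
                 score = res$score, params = params[c("gap_open", "gap_extend")],
                 mode = "global"),
            class = "alignment_result")
}

#' Local pairwise alignment (Smith-Waterman, affine gaps)
#'
#' @inheritParams align_global
#' @return An `alignment_result` with additional 1-based inclusive hit
#'   coordinates `start_a`, `end_a`, `start_b`, `end_b`.
#' @export
align_local <- function(a, b, params = align_params()) {
  a <- validate_aa(a, "a"); b <- validate_aa(b, "b")
  res <- gotoh(a, b, params, "local")
  structure(list(aligned_a = res$aligned_a, aligned_b = res$aligned_b,
                 score = res$score,
                 start_a = res$start_a, end_a = res$end_a,
                 start_b = res$start_b, end_b = res$end_b,
                 params = params[c("gap_open", "gap_extend")],
                 mode = "local"),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> %s score=%g\n%s\n%s\n",
              x$mode, x$score, x$aligned_a, x$aligned_b))
  invisible(x)
}
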