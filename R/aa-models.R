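# Amino-acid alphabet and empirical substitution model constants.
#
# The JTT exchangeabilities and stationary frequencies below are the published
# Jones-Taylor-Thornton (1992) model in the conventional PAML residue order
# A R N D C Q E G H I L K M F P S T W Y V (lower triangle, row-wise).

AA_LEVELS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Letters accepted in a ProteinRecord sequence ('-' only inside alignments).
AA_VALID <- c(AA_LEVELS, "X")

JTT_LOWER <- c(
  58, 54, 81, 56, 57, 105, 179, 27, 36, 30, 35, 54, 15, 194, 378, 475, 9, 11,
  298, 45, 16, 113, 310, 29, 137, 328, 22, 38, 646, 44, 5, 74, 101, 64, 126,
  20, 17, 528, 34, 86, 58, 81, 391, 47, 12, 263, 30, 10, 15, 503, 232, 8, 70,
  16, 10, 49, 767, 130, 112, 11, 7, 26, 15, 4, 15, 59, 38, 4, 46, 31, 9, 5,
  59, 69, 17, 23, 7, 31, 78, 14, 223, 42, 115, 209, 62, 323, 26, 597, 9, 72,
  292, 43, 4, 164, 53, 51, 18, 24, 20, 119, 26, 12, 9, 181, 18, 5, 18, 30,
  32, 10, 7, 45, 23, 6, 6, 27, 14, 5, 24, 201, 33, 55, 8, 47, 16, 56, 45, 33,
  40, 115, 73, 46, 8, 573, 11, 229, 21, 479, 89, 10, 40, 245, 9, 32, 961, 14,
  388, 248, 102, 59, 25, 52, 24, 180, 65, 4, 21, 47, 103, 10, 8, 14, 43, 16,
  29, 226, 24, 18, 323, 17, 92, 12, 53, 536, 62, 285, 118, 6, 10, 23, 477,
  35, 63, 38, 12, 21, 112, 71, 25, 16)

JTT_FREQS <- c(
  0.07674792325, 0.05169094831, 0.04264495736, 0.05154394846, 0.0198029802,
  0.04075195925, 0.06182993817, 0.07315192685, 0.02294397706, 0.05376094624,
  0.0919039081, 0.05867594132, 0.02382597617, 0.04012595987, 0.0509009491,
  0.06876493124, 0.05856494144, 0.01426098574, 0.0321019679, 0.066004934)
names(JTT_FREQS) <- AA_LEVELS

#' JTT instantaneous rate matrix
#'
#' Builds the 20x20 JTT rate matrix `Q` from the published exchangeabilities
#' and stationary frequencies, calibrated so that one unit of branch length
#' equals one expected substitution per site at stationarity.
#'
#' @return List with `Q` (rate matrix), `pi` (stationary frequencies) and the
#'   symmetric eigendecomposition (`values`, `vectors`, `inv`) used to compute
#'   transition probabilities.
#' @export
jtt_model <- function() {
  if (!is.null(.jtt_cache$model)) return(.jtt_cache$model)
  n <- 20L
  S <- matrix(0, n, n, dimnames = list(AA_LEVELS, AA_LEVELS))
  S[upper.tri(S)] <- 0
  k <- 1L
  for (i in 2:n) for (j in 1:(i - 1L)) {
    S[i, j] <- S[j, i] <- JTT_LOWER[k]
    k <- k + 1L
  }
  pi <- JTT_FREQS
  Q <- S * rep(pi, each = n)      # Q_ij = S_ij * pi_j
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))        # expected substitutions per unit time
  Q <- Q / mu
  # symmetric form B = D^1/2 Q D^-1/2 for a stable eigendecomposition
  sq <- sqrt(pi)
  B <- Q * (sq %o% (1 / sq))
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  vectors <- eig$vectors / sq       # D^-1/2 U
  inv <- t(eig$vectors) * rep(sq, each = n)  # U' D^1/2
  model <- list(Q = Q, pi = pi, values = eig$values,
                vectors = vectors, inv = inv)
  .jtt_cache$model <- model
  model
}

.jtt_cache <- new.env(parent = emptyenv())

#' JTT transition probability matrix
#'
#' @param t branch length in expected substitutions per site (>= 0).
#' @return 20x20 matrix `P(t)` with rows = ancestral residue.
#' @export
jtt_prob <- function(t) {
  assert_scalar_num(t, "t", lower = 0)
  m <- jtt_model()
  P <- m$vectors %*% (exp(m$values * t) * m$inv)
  P[P < 0] <- 0                      # clip tiny negative round-off
  dimnames(P) <- list(AA_LEVELS, AA_LEVELS)
  P
}

# BLOSUM62 restricted to the 20 canonical residues plus X (from Biostrings).
blosum62 <- function() {
  if (is.null(.jtt_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    keep <- c(AA_LEVELS, "X")
    .jtt_cache$blosum62 <- e$BLOSUM62[keep, keep]
  }
  .jtt_cache$blosum62
}

aa_index <- function(chars, field = "sequence") {
  idx <- match(chars, AA_LEVELS)
  idx
}
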