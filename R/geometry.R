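# The spatial embedding metric: per-linker-residue octant occupancy of
# ligand heavy atoms around each Calpha, threading classification, model
# placement QC, and the minimal-bivalent-linker cutoff.

#' Embedding metric parameters
#'
#' A linker residue counts as embedded in the ligand when ligand heavy atoms
#' within `radius` of its Calpha occupy at least `min_octants` of the eight
#' octants around it. Boundary rules are deterministic: the radius is
#' inclusive, and an atom lying on an octant plane (zero coordinate) is
#' assigned the positive half-space of that axis.
#'
#' @param radius neighbourhood radius in Angstrom (default 5).
#' @param min_octants octant threshold (1..8, default 5).
#' @param frame `"global"` (axis-aligned octants, default) or `"ligand_pca"`
#'   (octant axes = principal axes of the ligand heavy atoms, which makes
#'   counts covariant under joint rotation).
#' @export
embedding_params <- function(radius = 5.0, min_octants = 5L,
                             frame = c("global", "ligand_pca")) {
  frame <- match.arg(frame)
  assert_scalar_num(radius, "radius", lower = 0, strict = TRUE)
  if (!is.numeric(min_octants) || min_octants < 1 || min_octants > 8)
    abort_field("min_octants", "must be in 1..8")
  list(radius = radius, min_octants = as.integer(min_octants), frame = frame)
}

#' Linker residue span on the receptor chain
#'
#' @param start,end first and last residue numbers (inclusive, contiguous).
#' @param how `"motif"` (found by core-sequence matching) or `"explicit"`.
#' @export
linker_span <- function(start, end, how = c("explicit", "motif")) {
  how <- match.arg(how)
  if (end < start) abort_field("span", "end must be >= start")
  structure(list(start = as.integer(start), end = as.integer(end),
                 length = as.integer(end - start + 1L), how = how),
            class = "linker_span")
}

#' Locate the inter-domain linker by its core sequence
#'
#' Finds the unique exact occurrence of the linker core sequence in the
#' receptor sequence and extends the span outward through maximal contiguous
#' runs of the flanking extension letters (G/S by default) on both sides.
#'
#' @param receptor_sequence amino-acid string (e.g. from
#'   [model_receptor_sequence()]).
#' @param core core linker sequence; the default is the canonical 20-residue
#'   core encoded at the junction of the duplicated exon pair.
#' @param flank_residues letters allowed in the flanking extensions.
#' @return a [linker_span()] (1-based residue positions in the sequence).
#' @export
find_linker <- function(receptor_sequence,
                        core = "SESVNNDMIVTDNNGAVKFP",
                        flank_residues = "GS") {
  if (!nzchar(core)) abort_field("core", "must be non-empty")
  receptor_sequence <- toupper(receptor_sequence)
  hits <- gregexpr(core, receptor_sequence, fixed = TRUE)[[1]]
  if (hits[1] == -1L)
    stop("linker core sequence not found in receptor sequence", call. = FALSE)
  if (length(hits) > 1L)
    stop(sprintf("linker core sequence is ambiguous (%d matches)",
                 length(hits)), call. = FALSE)
  start <- as.integer(hits[1])
  end <- start + nchar(core) - 1L
  chars <- strsplit(receptor_sequence, "", fixed = TRUE)[[1]]
  flank <- strsplit(toupper(flank_residues), "", fixed = TRUE)[[1]]
  while (start > 1L && chars[start - 1L] %in% flank) start <- start - 1L
  while (end < length(chars) && chars[end + 1L] %in% flank) end <- end + 1L
  linker_span(start, end, how = "motif")
}

# rotation applied to displacement vectors before octant assignment
frame_rotation <- function(lig, params) {
  if (params$frame == "global" || nrow(lig) < 3) return(diag(3))
  xyz <- as.matrix(lig[, c("x", "y", "z")])
  pc <- stats::prcomp(xyz, center = TRUE, scale. = FALSE)
  W <- pc$rotation
  # deterministic sign convention: largest-|loading| component positive
  for (k in 1:3) {
    m <- which.max(abs(W[, k]))
    if (W[m, k] < 0) W[, k] <- -W[, k]
  }
  t(W)
}

#' Octant occupancy profile of a linker
#'
#' For every linker residue, ligand heavy atoms within `radius` of its
#' Calpha (inclusive) are assigned to the octant given by the sign pattern
#' of their displacement in the chosen frame; the residue's octant count is
#' the number of distinct occupied octants and the residue is embedded when
#' the count reaches `min_octants`.
#'
#' @param model a `structure_model`.
#' @param span a [linker_span()] on the receptor chain.
#' @param params an [embedding_params()].
#' @return `embedding_profile`: list with `model_id`, `rank`,
#'   `linker_length`, `per_residue` (data.frame `resseq`, `octant_count`,
#'   `embedded`) and `n_embedded`.
#' @export
octant_counts <- function(model, span, params = embedding_params()) {
  lig <- ligand_heavy_atoms(model)
  ca <- receptor_ca(model)
  ca <- ca[ca$resseq >= span$start & ca$resseq <= span$end, , drop = FALSE]
  missing <- setdiff(span$start:span$end, ca$resseq)
  if (length(missing))
    stop("missing Calpha for residue(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  R <- frame_rotation(lig, params)
  lxyz <- as.matrix(lig[, c("x", "y", "z")])
  counts <- integer(nrow(ca))
  r2 <- params$radius^2
  for (i in seq_len(nrow(ca))) {
    if (nrow(lxyz) == 0) next
    D <- lxyz - matrix(c(ca$x[i], ca$y[i], ca$z[i]), nrow(lxyz), 3,
                       byrow = TRUE)
    keep <- rowSums(D * D) <= r2
    if (!any(keep)) next
    V <- D[keep, , drop = FALSE] %*% t(R)
    oct <- 1L + (V[, 1] < 0) + 2L * (V[, 2] < 0) + 4L * (V[, 3] < 0)
    counts[i] <- length(unique(oct))
  }
  per <- data.frame(resseq = ca$resseq, octant_count = counts,
                    embedded = counts >= params$min_octants)
  structure(list(model_id = model$id, rank = model$rank,
                 linker_length = span$length, per_residue = per,
                 n_embedded = sum(per$embedded)),
            class = "embedding_profile")
}

#' @export
print.embedding_profile <- function(x, ...) {
  cat(sprintf("<embedding_profile> %s (rank %d): linker %d, %d embedded\n",
              x$model_id, x$rank, x$linker_length, x$n_embedded))
  invisible(x)
}

#' Does a model thread through the ligand?
#'
#' A model is classified as threading when at least `min_embedded` linker
#' residues are embedded (default 1; the full profile is always available
#' for alternative thresholds).
#' @param profile an `embedding_profile`.
#' @param min_embedded threshold on embedded residues.
#' @export
is_threading <- function(profile, min_embedded = 1L) {
  profile$n_embedded >= min_embedded
}

#' Rigid translation of a whole model (test utility)
#' @param model a `structure_model`.
#' @param shift numeric length-3 translation in Angstrom.
#' @export
shift_model <- function(model, shift) {
  model$atoms$x <- model$atoms$x + shift[1]
  model$atoms$y <- model$atoms$y + shift[2]
  model$atoms$z <- model$atoms$z + shift[3]
  model
}

#' Exclude models with misplaced receptor domains
#'
#' A model is kept iff, for every receptor LBD named in the placement spec,
#' the minimum heavy-atom distance between that LBD's atoms and its assigned
#' ligand epitope residues is at most `max_dist`.
#'
#' @param models list of `structure_model`s.
#' @param placement_spec data.frame: `lbd`, `rec_start`, `rec_end` (receptor
#'   residue range) and `lig_resseq` (comma-separated ligand residue
#'   numbers).
#' @param max_dist acceptance distance in Angstrom (default 8).
#' @return list: `kept` (models), `log` (data.frame `model`, `lbd`,
#'   `min_dist`, `kept`).
#' @export
filter_misplaced_models <- function(models, placement_spec, max_dist = 8) {
  if (!length(models)) return(list(kept = list(), log = data.frame()))
  logs <- list()
  kept <- list()
  for (model in models) {
    ok <- TRUE
    for (i in seq_len(nrow(placement_spec))) {
      rec <- model$atoms[model$atoms$chain == model$receptor_chain &
                           model$atoms$resseq >= placement_spec$rec_start[i] &
                           model$atoms$resseq <= placement_spec$rec_end[i] &
                           model$atoms$element != "H", , drop = FALSE]
      lig_res <- as.integer(strsplit(as.character(
        placement_spec$lig_resseq[i]), ",")[[1]])
      lig <- ligand_heavy_atoms(model)
      lig <- lig[lig$resseq %in% lig_res, , drop = FALSE]
      if (!nrow(rec) || !nrow(lig))
        stop(sprintf("placement spec row %d ('%s') references absent residues",
                     i, placement_spec$lbd[i]), call. = FALSE)
      d2 <- outer(rec$x, lig$x, "-")^2 + outer(rec$y, lig$y, "-")^2 +
        outer(rec$z, lig$z, "-")^2
      mind <- sqrt(min(d2))
      pass <- mind <= max_dist
      logs[[length(logs) + 1L]] <- data.frame(model = model$id,
                                              lbd = placement_spec$lbd[i],
                                              min_dist = mind, kept = pass)
      if (!pass) ok <- FALSE
    }
    if (ok) kept[[length(kept) + 1L]] <- model
  }
  list(kept = kept, log = do.call(rbind, logs))
}

#' Minimal linker length compatible with non-threading predictions
#'
#' Given embedding profiles grouped by linker length, returns the smallest
#' length whose `top_n` best-ranked models all have zero embedded residues
#' (the predicted cutoff for intra-ligand bivalency). Lengths with fewer
#' than `top_n` models are skipped with a warning; `NA` (with a `status`
#' attribute) when no length qualifies.
#'
#' @param profiles list of `embedding_profile`s.
#' @param top_n number of ranked models per length to require (default 3).
#' @export
min_bivalent_linker <- function(profiles, top_n = 3L) {
  if (!length(profiles)) {
    out <- NA_integer_; attr(out, "status") <- "no profiles"; return(out)
  }
  lens <- as.numeric(vapply(profiles, `[[`, numeric(1), "linker_length"))
  for (L in sort(unique(lens))) {
    grp <- profiles[lens == L]
    if (length(grp) < top_n) {
      warning(sprintf("linker length %d skipped: %d model(s) < top_n = %d",
                      L, length(grp), top_n), call. = FALSE)
      next
    }
    grp <- grp[order(vapply(grp, `[[`, numeric(1), "rank"))]
    grp <- grp[seq_len(top_n)]
    if (all(vapply(grp, `[[`, numeric(1), "n_embedded") == 0))
      return(as.integer(L))
  }
  out <- NA_integer_
  attr(out, "status") <- "no linker length with top-ranked non-threading models"
  out
}

#' Classify species linker lengths against the bivalency cutoff
#'
#' @param lengths data.frame with columns `species` and `linker_length` (or
#'   a named numeric vector).
#' @param cutoff minimal linker length for intra-ligand bivalency; a linker
#'   is feasible when `linker_length >= cutoff`.
#' @return data.frame: `species`, `linker_length`, `feasible`.
#' @export
compare_to_cutoff <- function(lengths, cutoff) {
  assert_scalar_num(cutoff, "cutoff", lower = 0)
  if (!is.data.frame(lengths))
    lengths <- data.frame(species = names(lengths),
                          linker_length = as.numeric(lengths))
  if (any(lengths$linker_length < 0))
    abort_field("lengths", "linker lengths must be >= 0")
  lengths$feasible <- lengths$linker_length >= cutoff
  lengths
}
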