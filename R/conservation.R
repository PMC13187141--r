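# Intra-protein LBD identity profiles and ligand-contact epitope retention.

#' Percent identity between two sequences
#'
#' Sequences are globally aligned ([align_global()]); identity is
#' `100 * identical columns / denominator`. The default denominator counts
#' only mutually ungapped columns (pairwise-deletion style, consistent with
#' the distance module); `denominator = "full"` divides by the full alignment
#' length instead. Rounding happens only at presentation.
#'
#' @param a,b amino-acid sequences.
#' @param params see [align_params()].
#' @param denominator `"ungapped"` (default) or `"full"`.
#' @return numeric percentage in `[0, 100]`.
#' @export
identity_pct <- function(a, b, params = align_params(),
                         denominator = c("ungapped", "full")) {
  denominator <- match.arg(denominator)
  al <- align_global(a, b, params)
  ca <- strsplit(al$aligned_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(al$aligned_b, "", fixed = TRUE)[[1]]
  both <- ca != "-" & cb != "-"
  if (!any(both))
    stop("identity undefined: no mutually ungapped columns", call. = FALSE)
  ident <- sum(ca == cb & both)
  denom <- if (denominator == "ungapped") sum(both) else length(ca)
  100 * ident / denom
}

#' Intra-protein identity profile relative to the inner LBD
#'
#' Computes [identity_pct()] of every annotated domain copy against the
#' membrane-proximal copy (label `in`); the `in` entry is exactly 100.
#'
#' @param protein a [protein_record()].
#' @param annotations `domain_annotation` data.frame with >= 2 rows.
#' @param params,denominator passed to [identity_pct()].
#' @return data.frame `identity_profile`: `protein_id`, `label`,
#'   `order_index`, `identity_pct`.
#' @export
identity_profile <- function(protein, annotations, params = align_params(),
                             denominator = "ungapped") {
  if (nrow(annotations) < 2L)
    stop("single-LBD protein: nothing to compare to the inner LBD",
         call. = FALSE)
  seqs <- domain_sequences(protein, annotations)
  ref <- seqs[[which(annotations$label == "in")]]
  pct <- vapply(seq_along(seqs), function(i) {
    if (annotations$label[i] == "in") return(100)
    identity_pct(seqs[[i]], ref, params, denominator)
  }, numeric(1))
  out <- data.frame(protein_id = annotations$protein_id,
                    label = annotations$label,
                    order_index = annotations$order_index,
                    identity_pct = pct)
  class(out) <- c("identity_profile", "data.frame")
  out
}

domain_sequences <- function(protein, annotations) {
  lapply(seq_len(nrow(annotations)), function(i)
    substr(protein$sequence, annotations$start[i] + 1L, annotations$end[i]))
}

#' Read an epitope specification TSV
#'
#' Columns: `group`, `ref_pos_1based`, `contact_type` (`polar` or
#' `hydrophobic`). Positions are 1-based on the reference LBD and must be
#' unique.
#' @param path TSV file.
#' @export
read_epitope_spec <- function(path) {
  df <- read_tsv(path)
  need <- c("group", "ref_pos_1based", "contact_type")
  if (!all(need %in% names(df)))
    abort_field("epitope spec", paste("missing column(s):",
                paste(setdiff(need, names(df)), collapse = ", ")))
  validate_epitope_spec(df)
}

validate_epitope_spec <- function(spec) {
  if (anyDuplicated(spec$ref_pos_1based))
    abort_field("epitope spec", "duplicate reference positions")
  if (any(spec$ref_pos_1based < 1))
    abort_field("epitope spec", "positions must be >= 1")
  if (!all(spec$contact_type %in% c("polar", "hydrophobic")))
    abort_field("epitope spec", "contact_type must be polar or hydrophobic")
  spec
}

#' Epitope retention of a target LBD relative to a reference
#'
#' Aligns the target to the reference ([align_global()]); for each site-class
#' group a reference position is "retained" when the aligned target column
#' carries the identical residue (`mode = "strict"`, default) or any
#' positive-BLOSUM62 substitution (`mode = "similar"`). Positions aligned to
#' a gap are never retained.
#'
#' @param target_lbd,reference_lbd sequences.
#' @param spec epitope specification data.frame
#'   (`group`, `ref_pos_1based`, `contact_type`).
#' @param mode `"strict"` or `"similar"`.
#' @param params see [align_params()].
#' @return data.frame `retention_score`: `group`, `retained_count`,
#'   `total_count`, `fraction`, `percent`.
#' @export
epitope_retention <- function(target_lbd, reference_lbd, spec,
                              mode = c("strict", "similar"),
                              params = align_params()) {
  mode <- match.arg(mode)
  spec <- validate_epitope_spec(spec)
  reference_lbd <- validate_aa(reference_lbd, "reference_lbd")
  if (any(spec$ref_pos_1based > nchar(reference_lbd)))
    abort_field("epitope spec",
                "position beyond reference length")
  al <- align_global(reference_lbd, target_lbd, params)
  cr <- strsplit(al$aligned_a, "", fixed = TRUE)[[1]]
  ct <- strsplit(al$aligned_b, "", fixed = TRUE)[[1]]
  # map reference positions to alignment columns
  ref_col <- which(cr != "-")
  sub <- blosum62()
  retained_at <- function(pos) {
    col <- ref_col[pos]
    if (ct[col] == "-" || ct[col] == "X") return(FALSE)
    if (mode == "strict") return(ct[col] == cr[col])
    sub[cr[col], ct[col]] > 0
  }
  groups <- unique(spec$group)
  rows <- lapply(groups, function(g) {
    pos <- spec$ref_pos_1based[spec$group == g]
    ret <- sum(vapply(pos, retained_at, logical(1)))
    data.frame(group = g, retained_count = ret, total_count = length(pos),
               fraction = ret / length(pos), percent = 100 * ret / length(pos))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("retention_score", "data.frame")
  out
}
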