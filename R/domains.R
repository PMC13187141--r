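# Tandem LBD annotation by iterative masked local alignment, positional
# labelling (out / mid / in), and exon-junction linker arithmetic.
#
# Coordinates are 0-based half-open internally; every report and file output
# is 1-based inclusive.

#' Domain detection parameters
#'
#' The detection threshold is expressed as a fraction of the reference
#' self-score (BLOSUM62 self-alignment), and the minimum hit length as a
#' fraction of the reference length. Neither value is asserted by any
#' published source; both are exposed here.
#'
#' @param min_score_frac hit-score threshold as fraction of self-score.
#' @param min_len_frac minimum hit length as fraction of reference length.
#' @param align see [align_params()].
#' @export
detect_params <- function(min_score_frac = 0.4, min_len_frac = 0.5,
                          align = align_params()) {
  assert_scalar_num(min_score_frac, "min_score_frac", lower = 0)
  assert_scalar_num(min_len_frac, "min_len_frac", lower = 0)
  list(min_score_frac = min_score_frac, min_len_frac = min_len_frac,
       align = align)
}

self_score <- function(sequence, params = align_params()) {
  idx <- match(strsplit(sequence, "", fixed = TRUE)[[1]],
               rownames(params$submat))
  sum(params$submat[cbind(idx, idx)])
}

#' Detect tandem domain copies on a protein
#'
#' Iterative Smith-Waterman of a reference domain against the protein: after
#' each hit scoring at least the threshold, the hit span is masked and the
#' scan repeats, so copies are found one by one and can never overlap. Hits
#' are sorted N->C and labelled by membrane proximity: the most C-terminal
#' copy is `in`, the most N-terminal (of >= 2) is `out`, any others `mid`
#' (`mid1`, `mid2`, ... N->C when more than three copies are present).
#'
#' @param protein a [protein_record()] (or plain sequence string).
#' @param reference_lbd reference domain sequence, length >= 30.
#' @param params see [detect_params()].
#' @return data.frame of class `domain_annotation` with columns `protein_id`,
#'   `start`, `end` (0-based half-open), `start_1based`, `end_1based`,
#'   `order_index`, `label`, `score`. Zero rows when nothing is found.
#' @export
detect_tandem_domains <- function(protein, reference_lbd,
                                  params = detect_params()) {
  if (is.character(protein)) protein <- protein_record("query", protein)
  reference_lbd <- validate_aa(reference_lbd, "reference_lbd")
  if (nchar(reference_lbd) < 30)
    abort_field("reference_lbd", "must be at least 30 residues")
  seq <- protein$sequence
  threshold <- params$min_score_frac * self_score(reference_lbd, params$align)
  min_len <- max(1L, floor(params$min_len_frac * nchar(reference_lbd)))

  hits <- list()
  masked <- seq
  repeat {
    al <- align_local(reference_lbd, masked, params$align)
    hit_len <- al$end_b - al$start_b + 1L
    if (al$score < threshold || hit_len < min_len || nchar(al$aligned_b) == 0)
      break
    hits[[length(hits) + 1L]] <- list(start = al$start_b - 1L, end = al$end_b,
                                      score = al$score)
    # mask the hit span with X so it cannot be found again; X scores are
    # non-positive in BLOSUM62, and each round removes >= min hit length
    substr(masked, al$start_b, al$end_b) <-
      strrep("X", al$end_b - al$start_b + 1L)
  }
  if (!length(hits)) {
    out <- data.frame(protein_id = character(), start = integer(),
                      end = integer(), start_1based = integer(),
                      end_1based = integer(), order_index = integer(),
                      label = character(), score = numeric())
    class(out) <- c("domain_annotation", "data.frame")
    return(out)
  }
  out <- data.frame(protein_id = protein$id,
                    start = vapply(hits, `[[`, integer(1), "start"),
                    end = vapply(hits, `[[`, integer(1), "end"),
                    score = vapply(hits, `[[`, numeric(1), "score"))
  out <- out[order(out$start), , drop = FALSE]
  n <- nrow(out)
  out$order_index <- seq_len(n)
  out$label <- domain_labels(n)
  out$start_1based <- out$start + 1L
  out$end_1based <- out$end
  rownames(out) <- NULL
  out <- out[, c("protein_id", "start", "end", "start_1based", "end_1based",
                 "order_index", "label", "score")]
  class(out) <- c("domain_annotation", "data.frame")
  out
}

#' Positional labels for n tandem copies (N->C order)
#'
#' One copy: `in`. Two: `out`, `in`. Three: `out`, `mid`, `in`. More: `out`,
#' `mid1`..`midK`, `in` (covers five-copy architectures).
#' @param n number of copies.
#' @export
domain_labels <- function(n) {
  if (n == 1L) return("in")
  if (n == 2L) return(c("out", "in"))
  if (n == 3L) return(c("out", "mid", "in"))
  c("out", paste0("mid", seq_len(n - 2L)), "in")
}

#' Inter-domain linker lengths
#'
#' Number of residues strictly between the end of each domain copy and the
#' start of the next (N->C adjacent pairs); for a receptor whose duplication
#' copies an exon pair, this is the stretch encoded at the junction of the
#' original and duplicated exons.
#'
#' @param annotations a `domain_annotation` data.frame with >= 2 rows.
#' @return data.frame with columns `from_label`, `to_label`, `linker_length`;
#'   or `NA` with a `status` attribute when fewer than two annotations exist.
#' @export
linker_length_from_domains <- function(annotations) {
  if (nrow(annotations) < 2L) {
    out <- NA_integer_
    attr(out, "status") <- "fewer than two domain annotations; no linker"
    return(out)
  }
  ann <- annotations[order(annotations$start), , drop = FALSE]
  if (any(ann$end[-nrow(ann)] > ann$start[-1]))
    abort_field("annotations", "domain annotations overlap")
  data.frame(from_label = ann$label[-nrow(ann)],
             to_label = ann$label[-1],
             linker_length = ann$start[-1] - ann$end[-nrow(ann)])
}

#' Write domain annotations as TSV (1-based inclusive coordinates)
#' @param annotations `domain_annotation` data.frame.
#' @param path output file.
#' @export
write_domain_tsv <- function(annotations, path) {
  df <- data.frame(protein_id = annotations$protein_id,
                   start_1based = annotations$start_1based,
                   end_1based = annotations$end_1based,
                   order = annotations$order_index,
                   label = annotations$label,
                   score = annotations$score)
  write_tsv(df, path)
}
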