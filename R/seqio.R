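# Protein records and FASTA I/O.

#' Create a protein record
#'
#' A `protein_record` carries an identifier, optional species/clade tags and a
#' validated amino-acid sequence (20 canonical letters plus `X`; the gap
#' character `-` is only legal inside alignments, never in a record).
#'
#' @param id non-empty identifier.
#' @param sequence amino-acid string.
#' @param species,clade optional annotation tags.
#' @return Object of class `protein_record`.
#' @export
protein_record <- function(id, sequence, species = NA_character_,
                           clade = NA_character_) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    abort_field("id", "must be a non-empty string")
  sequence <- validate_aa(sequence, id = id)
  structure(list(id = id, species = species, clade = clade,
                 sequence = sequence),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s (%d aa)%s\n", x$id, nchar(x$sequence),
              if (is.na(x$species)) "" else paste0(" [", x$species, "]")))
  invisible(x)
}

validate_aa <- function(sequence, id = "?", allow_gap = FALSE) {
  if (!is.character(sequence) || length(sequence) != 1L)
    abort_field("sequence", "must be a single string")
  sequence <- toupper(sequence)
  if (!nzchar(sequence))
    abort_field("sequence", sprintf("empty sequence for record '%s'", id))
  ok <- AA_VALID
  if (allow_gap) ok <- c(ok, "-")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), ok)
  if (length(bad))
    abort_field("sequence",
                sprintf("record '%s' contains invalid letter(s): %s",
                        id, paste(bad, collapse = ", ")))
  sequence
}

#' Read protein FASTA
#'
#' @param path FASTA file. An empty file yields an empty list.
#' @return List of [protein_record()]s, named by id. The FASTA description up
#'   to the first whitespace becomes the id.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0) return(structure(list(), names = character()))
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  recs <- lapply(seq_along(set), function(i)
    protein_record(ids[i], as.character(set[[i]])))
  names(recs) <- ids
  recs
}

#' Write protein FASTA
#'
#' @param records list of [protein_record()]s.
#' @param path output file.
#' @export
write_fasta <- function(records, path) {
  records <- as_records(records)
  lines <- unlist(lapply(records, function(r) c(paste0(">", r$id), r$sequence)))
  if (is.null(lines)) lines <- character()
  writeLines(lines, path)
  invisible(path)
}

as_records <- function(records) {
  if (inherits(records, "protein_record")) return(list(records))
  if (!is.list(records) ||
      !all(vapply(records, inherits, logical(1), "protein_record")))
    abort_field("records", "must be a list of protein_record objects")
  records
}
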