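# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

abort_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

assert_scalar_num <- function(x, field, lower = -Inf, strict = FALSE,
                              allow_inf = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    abort_field(field, "must be a single non-missing number")
  if (!allow_inf && !is.finite(x)) abort_field(field, "must be finite")
  if (strict && x <= lower)
    abort_field(field, sprintf("must be > %s", lower))
  if (!strict && x < lower)
    abort_field(field, sprintf("must be >= %s", lower))
  invisible(x)
}

assert_flag <- function(x, field) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    abort_field(field, "must be TRUE or FALSE")
  invisible(x)
}

# FNV-1a 32-bit hash of a character scalar; used to fingerprint configs and to
# derive per-stage RNG substreams without external dependencies.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte (b < 256); h can exceed .Machine integers
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), as.integer(b %% 256))
    # multiply by 16777619 mod 2^32 using double arithmetic on half-words
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- ((lo * 16777619) + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  h
}

# Deterministic 31-bit substream seed from a master seed and a stage label.
substream_seed <- function(seed, label) {
  as.integer((fnv1a32(paste0(label, ":", seed)) + seed) %% 2147483647)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}
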