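## internal helpers shared across modules

#' Reverse complement of plain character DNA sequences
#'
#' Thin vectorised wrapper around the package's C++ kernel. Ambiguous or
#' non-ACGT characters become N.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @examples
#' revComp("ACGTT")
#' @export
revComp <- function(x) {
  stopifnot(is.character(x))
  cpp_revcomp(toupper(x))
}

.checkDna <- function(x, what = "sequence", allow_n = TRUE) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) == 0L)
    stop(what, " must be a non-empty character scalar", call. = FALSE)
  x <- toupper(x)
  alph <- if (allow_n) "ACGTN" else "ACGT"
  if (grepl(sprintf("[^%s]", alph), x))
    stop(what, " contains characters outside {", alph, "}", call. = FALSE)
  x
}

## derive a per-stage seed from a global one; keeps every stage independently
## reproducible while staying inside 32-bit integer range
.deriveSeed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

.withSeed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(seed)
  expr
}

## FASTQ I/O via Biostrings; constant qualities are enough for this pipeline
.readFastq <- function(path) {
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) stop("malformed FASTQ '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  x
}

.writeFastq <- function(seqs, path, qualities = NULL) {
  x <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(x))) names(x) <- paste0("read", seq_along(x))
  if (is.null(qualities))
    qualities <- vapply(Biostrings::width(x), function(w)
      paste(rep("I", w), collapse = ""), character(1))
  q <- Biostrings::BStringSet(qualities)
  Biostrings::writeXStringSet(x, filepath = path, format = "fastq",
                              qualities = q)
  invisible(path)
}
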