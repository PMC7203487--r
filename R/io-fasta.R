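#' Read a FASTA file into a BStringSet
#'
#' Records are returned in file order.  Names are truncated at the first
#' whitespace (the token used for GFF seqid matching); the full header is
#' kept in \code{mcols(x)$description}.  Case is preserved: soft-masked
#' (lowercase) bases are data, and rendering decides their treatment.
#'
#' @param path path to a (plain-text) FASTA file.
#' @return A \code{\link[Biostrings]{BStringSet}} with short names and a
#'   \code{description} metadata column.
#' @export
readFastaFile <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  head <- readLines(path, n = 50, warn = FALSE)
  head <- head[nzchar(trimws(head))]
  if (!length(head) || !startsWith(head[1], ">"))
    stopf("%s: not FASTA (first non-blank character must be '>')", path)
  x <- Biostrings::readBStringSet(path)
  if (any(Biostrings::width(x) == 0))
    stopf("%s: empty record(s): %s", path,
          paste(names(x)[Biostrings::width(x) == 0], collapse = ", "))
  full <- names(x)
  short <- sub("[[:space:]].*$", "", full)
  if (any(!nzchar(short))) stopf("%s: record with empty name", path)
  names(x) <- short
  S4Vectors::mcols(x) <- S4Vectors::DataFrame(description = full)
  x
}

#' Write sequences to a FASTA file
#'
#' @param x a \code{BStringSet} or named character vector.
#' @param path output path.
#' @param width line-wrap width.
#' @return \code{path}, invisibly.
#' @export
writeFastaFile <- function(x, path, width = 80) {
  if (is.character(x)) x <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}
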