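#' Read GFF3/GFF2/GTF annotations
#'
#' Parses a 9-column annotation file (via \code{rtracklayer::readGFF})
#' into a \code{GRanges}.  Coordinates stay 1-based inclusive (the
#' \code{GRanges} convention, identical to the GFF convention).  Each
#' feature gets:
#' \itemize{
#'   \item \code{ftype}: one of \code{gene, mRNA, exon, CDS, other}
#'     (unknown types map to \code{other}; \code{transcript} counts as
#'     \code{mRNA}).
#'   \item \code{label}: display name resolved by precedence
#'     \code{Name > ID > gene_id > gene_name}, else empty.
#' }
#'
#' @param path annotation file path.
#' @param dialect one of \code{"auto"}, \code{"gff3"}, \code{"gff2"},
#'   \code{"gtf"} (gff2 and gtf share the quoted-attribute syntax; with
#'   \code{"auto"} the dialect is detected from the attribute column).
#' @return A \code{\link[GenomicRanges]{GRanges}} with metadata columns
#'   \code{source}, \code{ftype}, \code{type}, \code{label}.
#' @export
readAnnotations <- function(path, dialect = c("auto", "gff3", "gff2", "gtf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  for (ln in body) {
    ncol <- length(strsplit(lines[ln], "\t", fixed = TRUE)[[1]])
    if (ncol < 9)
      stopf("%s line %d: %d columns, expected 9", path, ln, ncol)
  }
  version <- switch(dialect, gff3 = 3, gff2 = 2, gtf = 2, auto = 0)
  df <- if (version == 0) rtracklayer::readGFF(path)
        else rtracklayer::readGFF(path, version = version)
  df <- as.data.frame(df)
  bad <- which(df$end < df$start)
  if (length(bad))
    stopf("%s: end < start for feature(s) at row(s) %s", path,
          paste(utils::head(bad, 5), collapse = ", "))
  known <- c(gene = "gene", mRNA = "mRNA", transcript = "mRNA",
             exon = "exon", CDS = "CDS")
  rawType <- as.character(df$type)
  ftype <- unname(known[rawType])
  ftype[is.na(ftype)] <- "other"
  pick <- function(col) {
    v <- if (col %in% names(df)) as.character(df[[col]]) else
      rep(NA_character_, nrow(df))
    v[!is.na(v) & !nzchar(v)] <- NA_character_
    v
  }
  label <- pick("Name")
  for (col in c("ID", "gene_id", "gene_name")) {
    miss <- is.na(label)
    if (!any(miss)) break
    label[miss] <- pick(col)[miss]
  }
  label[is.na(label)] <- ""
  strand <- as.character(df$strand)
  strand[is.na(strand) | !strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(df$seqid),
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = as.character(df$source),
    ftype = factor(ftype, levels = c("gene", "mRNA", "exon", "CDS", "other")),
    type = rawType,
    label = label)
  gr
}
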