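## small shared helpers

# reverse-complement of a plain character string; preserves case,
# handles IUPAC ambiguity codes and '-'/N passthrough
revcompChr <- function(s) {
  from <- "ACGTUacgtuRYSWKMBDHVNryswkmbdhvn"
  to   <- "TGCAAtgcaaYRSWMKVHDBNyrswmkvhdbn"
  paste(rev(strsplit(chartr(from, to, s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# split a string into single characters
chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# maximal runs of TRUE in a logical vector -> data.frame(start, length),
# start 1-based
trueRuns <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  data.frame(start = starts[keep], length = r$lengths[keep])
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

isWholeNumber <- function(x) all(is.finite(x)) && all(x == floor(x))
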