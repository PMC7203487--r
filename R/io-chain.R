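#' Read a UCSC chain file
#'
#' Parses chained liftOver alignments.  Each chain header is
#' \code{chain score tName tSize tStrand tStart tEnd qName qSize qStrand
#' qStart qEnd id}, followed by block lines \code{size [dt dq]} (the last
#' block has no gaps).  All coordinates are 0-based half-open; query
#' coordinates of '-' strand chains are on the reverse-complemented
#' query.  Block arithmetic is verified against the header spans:
#' \code{sum(size + dt) == tEnd - tStart} and
#' \code{sum(size + dq) == qEnd - qStart}.
#'
#' @param path path to a plain-text chain file.
#' @return list of \linkS4class{Chain} objects in file order.
#' @export
readChainFile <- function(path) {
  if (!file.exists(path)) stopf("chain file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  chains <- list()
  i <- 1
  n <- length(lines)
  while (i <= n) {
    if (!nzchar(lines[i]) || startsWith(lines[i], "#")) { i <- i + 1; next }
    if (!startsWith(lines[i], "chain"))
      stopf("%s line %d: expected 'chain' header, got: %s", path, i, lines[i])
    f <- strsplit(lines[i], "[[:space:]]+")[[1]]
    if (length(f) != 13)
      stopf("%s line %d: chain header needs 13 fields, got %d", path, i,
            length(f))
    num <- function(k) as.numeric(f[k])
    hdr <- list(score = num(2), tName = f[3], tSize = num(4), tStrand = f[5],
                tStart = num(6), tEnd = num(7), qName = f[8], qSize = num(9),
                qStrand = f[10], qStart = num(11), qEnd = num(12),
                chainId = num(13))
    i <- i + 1
    blocks <- list()
    repeat {
      if (i > n || !nzchar(lines[i])) break
      v <- as.numeric(strsplit(lines[i], "[[:space:]]+")[[1]])
      if (any(is.na(v)) || !length(v) %in% c(1, 3))
        stopf("%s line %d: bad block line in chain %d", path, i, hdr$chainId)
      blocks[[length(blocks) + 1]] <-
        c(v[1], if (length(v) == 3) v[2:3] else c(0, 0))
      i <- i + 1
      if (length(v) == 1) break        # last block of the chain
    }
    b <- as.data.frame(do.call(rbind, blocks))
    names(b) <- c("size", "dt", "dq")
    ch <- new("Chain", score = hdr$score, tName = hdr$tName,
              tSize = hdr$tSize, tStrand = hdr$tStrand, tStart = hdr$tStart,
              tEnd = hdr$tEnd, qName = hdr$qName, qSize = hdr$qSize,
              qStrand = hdr$qStrand, qStart = hdr$qStart, qEnd = hdr$qEnd,
              chainId = hdr$chainId, blocks = b)
    v <- validObject(ch, test = TRUE)
    if (!isTRUE(v))
      stopf("%s: invalid chain %d: %s", path, hdr$chainId,
            paste(v, collapse = "; "))
    chains[[length(chains) + 1]] <- ch
  }
  chains
}

#' Write chains to a UCSC chain file
#'
#' Inverse of \code{\link{readChainFile}}: re-reading the output yields
#' identical field values.
#'
#' @param chains list of \linkS4class{Chain}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeChainFile <- function(chains, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in chains) {
    writeLines(sprintf("chain %.0f %s %.0f %s %.0f %.0f %s %.0f %s %.0f %.0f %.0f",
                       ch@score, ch@tName, ch@tSize, ch@tStrand, ch@tStart,
                       ch@tEnd, ch@qName, ch@qSize, ch@qStrand, ch@qStart,
                       ch@qEnd, ch@chainId), con)
    b <- ch@blocks
    nb <- nrow(b)
    if (nb > 1)
      writeLines(sprintf("%.0f %.0f %.0f", b$size[-nb], b$dt[-nb],
                         b$dq[-nb]), con)
    writeLines(sprintf("%.0f", b$size[nb]), con)
    writeLines("", con)
  }
  invisible(path)
}

setMethod("show", "Chain", function(object) {
  cat(sprintf(
    "Chain %d (score %.0f): %s:%.0f-%.0f (+) ~ %s:%.0f-%.0f (%s), %d blocks\n",
    object@chainId, object@score, object@tName, object@tStart, object@tEnd,
    object@qName, object@qStart, object@qEnd, object@qStrand,
    nrow(object@blocks)))
})

#' @describeIn readChainFile aligned-block target intervals of one chain
#'   as 0-based half-open \code{data.frame(tStart, tEnd, qStart, qEnd)}
#'   (query coordinates on the strand of the chain).
#' @param chain a \linkS4class{Chain}.
#' @export
chainBlockIntervals <- function(chain) {
  b <- chain@blocks
  tS <- chain@tStart + cumsum(c(0, b$size + b$dt))[seq_len(nrow(b))]
  qS <- chain@qStart + cumsum(c(0, b$size + b$dq))[seq_len(nrow(b))]
  data.frame(tStart = tS, tEnd = tS + b$size,
             qStart = qS, qEnd = qS + b$size)
}
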