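#' Construct a nested-radix tile layout
#'
#' The default layout arranges sequence in powers of ten: rows of 100
#' pixels (one base per pixel), columns of 1,000 rows (100 Kbp), 100
#' columns per mega-row (10 Mbp), 26 mega-rows per chromosome mega-column
#' (260 Mbp), and 999 mega-columns, with 3 px of whitespace between
#' columns, 9 px between mega-rows and 700 px between mega-columns:
#' radices \code{c(100, 1000, 100, 26, 999)} and paddings
#' \code{c(0, 0, 3, 9, 700)}.
#'
#' Levels alternate axes (level 1 = x, level 2 = y, ...).  Strides follow
#' the recurrence \code{stride[first level on axis] = 1 + padding} and
#' \code{stride[i] = radix[j]*stride[j] + padding[i]} with \code{j} the
#' previous level on the same axis.
#'
#' @param radices positive integers, one per level.
#' @param paddings non-negative integers, same length; trailing whitespace
#'   (pixels) after each unit of that level.
#' @return A \linkS4class{TileLayout}.
#' @examples
#' tl <- tileLayout()
#' capacity(tl)                     # 100*1000*100*26*999 bases
#' indexToPixel(tl, c(0, 99, 100))  # (0,0), (99,0), (0,1)
#' @export
tileLayout <- function(radices = c(100, 1000, 100, 26, 999),
                       paddings = c(0, 0, 3, 9, 700)) {
  if (length(radices) != length(paddings))
    stopf("radices (%d) and paddings (%d) must have equal length",
          length(radices), length(paddings))
  if (any(radices < 1)) stopf("all radices must be positive integers")
  if (any(paddings < 0)) stopf("paddings must be non-negative")
  radices <- as.numeric(radices); paddings <- as.numeric(paddings)
  n <- length(radices)
  strides <- numeric(n)
  lastOnAxis <- c(NA_integer_, NA_integer_)  # x, y
  for (i in seq_len(n)) {
    ax <- ((i - 1) %% 2) + 1                 # 1 = x, 2 = y
    j <- lastOnAxis[ax]
    strides[i] <- if (is.na(j)) 1 + paddings[i]
                  else radices[j] * strides[j] + paddings[i]
    lastOnAxis[ax] <- i
  }
  new("TileLayout", radices = radices, paddings = paddings,
      strides = strides, capacity = prod(radices))
}

#' @rdname tileLayout
#' @export
setMethod("capacity", "TileLayout", function(x) x@capacity)

#' @describeIn tileLayout per-level strides (pixels).
#' @export
strides <- function(x) x@strides

setMethod("show", "TileLayout", function(object) {
  cat("TileLayout with", length(object@radices), "levels\n")
  cat("  radices: ", paste(object@radices, collapse = ", "), "\n", sep = "")
  cat("  paddings:", paste(object@paddings, collapse = ", "), "\n")
  cat("  strides: ", paste(object@strides, collapse = ", "), "\n", sep = "")
  cat("  capacity:", format(object@capacity, big.mark = ","), "bases\n")
})

## mixed-radix digits of index i (vectorized over i): list of digit vectors
mixedDigits <- function(radices, i) {
  digits <- vector("list", length(radices))
  rem <- i
  for (k in seq_along(radices)) {
    digits[[k]] <- rem %% radices[k]
    rem <- rem %/% radices[k]
  }
  digits
}

#' @rdname indexToPixel
#' @export
setMethod("indexToPixel", "TileLayout", function(layout, i) {
  if (any(i < 0) || any(i >= layout@capacity))
    stopf("index out of range [0, %.0f)", layout@capacity)
  d <- mixedDigits(layout@radices, i)
  x <- 0; y <- 0
  for (k in seq_along(d)) {
    v <- d[[k]] * layout@strides[k]
    if (k %% 2 == 1) x <- x + v else y <- y + v
  }
  data.frame(x = x, y = y)
})

#' @rdname pixelToIndex
#' @export
setMethod("pixelToIndex", "TileLayout", function(layout, x, y) {
  n <- length(layout@radices)
  placeValue <- cumprod(c(1, layout@radices[-n]))
  idx <- numeric(length(x))
  ok <- x >= 0 & y >= 0
  resX <- x; resY <- y
  for (k in rev(seq_len(n))) {         # descending strides per axis
    onX <- k %% 2 == 1
    res <- if (onX) resX else resY
    d <- res %/% layout@strides[k]
    ok <- ok & d < layout@radices[k] & d >= 0
    res <- res - d * layout@strides[k]
    if (onX) resX <- res else resY <- res
    idx <- idx + d * placeValue[k]
  }
  # leftover residue means the pixel sits in intra-unit padding
  ok <- ok & resX == 0 & resY == 0
  idx[!ok] <- NA_real_
  idx
})

#' Place contigs into layout index space
#'
#' Contigs are laid out side by side: each contig starts at the next
#' column boundary (a multiple of \code{radices[1]*radices[2]} indices) so
#' its first base sits at the top of a fresh column; when a contig does
#' not fit in the remainder of the current mega-column it starts at the
#' next mega-column boundary, so several smaller contigs can share one
#' mega-column.
#'
#' @param contigs a \code{\link[Biostrings]{BStringSet}} (see
#'   \code{\link{readFastaFile}}) or named character vector.
#' @param layout a \linkS4class{TileLayout}.
#' @param sortContigs if TRUE, place in descending length order.
#' @return A \linkS4class{ContigMap}.
#' @export
placeContigs <- function(contigs, layout = tileLayout(), sortContigs = FALSE) {
  nms <- names(contigs)
  lens <- if (is.character(contigs)) nchar(contigs)
          else Biostrings::width(contigs)
  if (length(lens) == 0)
    return(new("ContigMap", entries = data.frame(
      name = character(), start = numeric(), length = numeric(),
      stringsAsFactors = FALSE)))
  if (is.null(nms) || any(!nzchar(nms)))
    stopf("all contigs must be named")
  if (sortContigs) {
    o <- order(lens, decreasing = TRUE)
    nms <- nms[o]; lens <- lens[o]
  }
  r <- layout@radices
  colCap <- r[1] * r[2]
  megaCap <- if (length(r) >= 4) colCap * r[3] * r[4] else layout@capacity
  cur <- 0
  starts <- numeric(length(lens))
  for (i in seq_along(lens)) {
    st <- ceiling(cur / colCap) * colCap
    megaEnd <- (st %/% megaCap + 1) * megaCap
    if (st + lens[i] > megaEnd)               # does not fit this mega-column
      st <- ceiling(st / megaCap) * megaCap
    if (st + lens[i] > layout@capacity)
      stopf("layout capacity %.0f exceeded placing contig '%s'",
            layout@capacity, nms[i])
    starts[i] <- st
    cur <- st + lens[i]
  }
  new("ContigMap", entries = data.frame(
    name = nms, start = starts, length = as.numeric(lens),
    stringsAsFactors = FALSE))
}

#' @describeIn placeContigs placement table accessor.
#' @param x a \code{ContigMap}.
#' @export
contigEntries <- function(x) x@entries

setMethod("show", "ContigMap", function(object) {
  cat("ContigMap with", nrow(object@entries), "contigs\n")
  print(utils::head(object@entries, 10))
  if (nrow(object@entries) > 10) cat("  ...\n")
})

## resolve a global layout index to (contig name, 0-based offset) or NULL
resolveIndex <- function(map, globalIndex) {
  e <- map@entries
  hit <- which(globalIndex >= e$start & globalIndex < e$start + e$length)
  if (!length(hit)) return(NULL)
  list(name = e$name[hit[1]], offset = globalIndex - e$start[hit[1]])
}

#' Extract a sequence snippet at a pixel
#'
#' Offline equivalent of mouseover sequence retrieval: resolves a pixel to
#' a global layout index, then to the owning contig and offset, and
#' returns the following \code{length} bases (default 300 bp), truncated
#' at the contig end.  Returns \code{NULL} for whitespace pixels or
#' pixels outside any placed contig.
#'
#' @param map a \linkS4class{ContigMap} from \code{\link{placeContigs}}.
#' @param layout the layout the map was built for.
#' @param contigs the sequences (\code{BStringSet} or named character).
#' @param x,y pixel coordinate (scalars).
#' @param length snippet length in bases (default 300).
#' @return \code{NULL}, or \code{list(name, offset, seq)} with a 0-based
#'   offset into the contig.
#' @export
extractSnippet <- function(map, layout, contigs, x, y, length = 300) {
  i <- pixelToIndex(layout, x, y)
  if (is.na(i)) return(NULL)
  hit <- resolveIndex(map, i)
  if (is.null(hit)) return(NULL)
  s <- if (is.character(contigs)) contigs[[hit$name]]
       else as.character(contigs[[hit$name]])
  from <- hit$offset + 1
  to <- min(hit$offset + length, nchar(s))
  list(name = hit$name, offset = hit$offset, seq = substr(s, from, to))
}

#' Parse a custom layout specification string
#'
#' Accepts the literal bracketed syntax
#' \code{"[(100,1000,100,26,999),(0,0,3,9,700)]"} (whitespace
#' insensitive): a radix tuple followed by a padding tuple.
#'
#' @param spec the specification string.
#' @return A \linkS4class{TileLayout}.
#' @export
parseCustomLayout <- function(spec) {
  s <- gsub("[[:space:]]", "", spec)
  m <- regmatches(s, gregexpr("\\(([0-9,]+)\\)", s))[[1]]
  if (length(m) != 2)
    stopf("custom layout must be \"[(r1,..,rn),(p1,..,pn)]\", got: %s", spec)
  nums <- lapply(m, function(t)
    as.numeric(strsplit(gsub("[()]", "", t), ",", fixed = TRUE)[[1]]))
  tileLayout(radices = nums[[1]], paddings = nums[[2]])
}
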