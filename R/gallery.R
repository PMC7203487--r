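#' Load a directory of multiple sequence alignments
#'
#' Each FASTA file in the directory is one MSA block: all records must
#' have equal (aligned) length.  Blocks are ordered alphabetically by
#' file name, or by descending record count with \code{sort = "by_count"}.
#'
#' @param dir directory containing FASTA files (.fa/.fasta/.fna).
#' @param sort \code{"alphabetical"} or \code{"by_count"}.
#' @return list of blocks: \code{list(name, rows)} with \code{rows} a
#'   character vector of aligned sequences.
#' @export
loadGallery <- function(dir, sort = c("alphabetical", "by_count")) {
  sort <- match.arg(sort)
  files <- sort(list.files(dir, pattern = "\\.(fa|fasta|fna)$",
                           full.names = TRUE))
  if (!length(files)) stopf("no FASTA files in %s", dir)
  blocks <- lapply(files, function(f) {
    x <- readFastaFile(f)
    wds <- Biostrings::width(x)
    if (length(unique(wds)) != 1)
      stopf("%s: ragged alignment (row lengths %s)", basename(f),
            paste(unique(wds), collapse = ", "))
    list(name = basename(f), rows = as.character(x))
  })
  if (sort == "by_count") {
    n <- vapply(blocks, function(b) length(b$rows), numeric(1))
    blocks <- blocks[order(n, decreasing = TRUE)]
  }
  blocks
}

#' Pack MSA blocks onto one gallery canvas
#'
#' Shelf packing: blocks go left to right, wrapping to a new shelf when
#' the canvas width would be exceeded; a fixed margin separates blocks
#' and \code{labelHeight} pixels above each block are reserved for its
#' file-name label.  Origins are recorded so any canvas pixel can be
#' mapped back to (file, record, alignment column).
#'
#' @param blocks from \code{\link{loadGallery}}.
#' @param maxWidth canvas width in pixels (default 4000).
#' @param margin inter-block margin (default 5).
#' @param labelHeight label strip above each block (default 10).
#' @return An \linkS4class{MSAGallery}.
#' @export
layoutGallery <- function(blocks, maxWidth = 4000, margin = 5,
                          labelHeight = 10) {
  widths <- vapply(blocks, function(b) nchar(b$rows[1]), numeric(1))
  heights <- vapply(blocks, function(b) length(b$rows), numeric(1))
  tooWide <- widths > maxWidth
  if (any(tooWide))
    stopf("block '%s' is %d px wide > maxWidth %d; increase maxWidth",
          blocks[[which(tooWide)[1]]]$name, widths[which(tooWide)[1]],
          maxWidth)
  x <- 0; y <- 0; shelfH <- 0
  ox <- numeric(length(blocks)); oy <- numeric(length(blocks))
  for (j in seq_along(blocks)) {
    bw <- widths[j]; bh <- heights[j] + labelHeight
    if (x > 0 && x + bw > maxWidth) {        # wrap to next shelf
      x <- 0; y <- y + shelfH + margin; shelfH <- 0
    }
    ox[j] <- x; oy[j] <- y + labelHeight
    shelfH <- max(shelfH, bh)
    x <- x + bw + margin
  }
  df <- data.frame(
    name = vapply(blocks, `[[`, character(1), "name"),
    width = widths, height = heights, x = ox, y = oy,
    stringsAsFactors = FALSE)
  new("MSAGallery", blocks = df,
      rows = lapply(blocks, `[[`, "rows"),
      width = max(df$x + df$width), height = y + shelfH,
      margin = margin, labelHeight = labelHeight)
}

setMethod("show", "MSAGallery", function(object) {
  cat(sprintf("MSAGallery: %d blocks on a %d x %d canvas\n",
              nrow(object@blocks), object@width, object@height))
})

#' Map a gallery pixel back to (file, record, column)
#'
#' @param gallery an \linkS4class{MSAGallery}.
#' @param x,y 0-based canvas pixel.
#' @return \code{NULL} for background/label pixels, else
#'   \code{list(name, row, column)} with 1-based row (record index) and
#'   column (alignment position).
#' @export
galleryLookup <- function(gallery, x, y) {
  b <- gallery@blocks
  hit <- which(x >= b$x & x < b$x + b$width &
               y >= b$y & y < b$y + b$height)
  if (!length(hit)) return(NULL)
  j <- hit[1]
  list(name = b$name[j], row = y - b$y[j] + 1, column = x - b$x[j] + 1)
}

#' Render an MSA gallery to a raster
#'
#' One pixel per aligned position, rows stacked per block, file-name
#' labels above each block.
#'
#' @param gallery an \linkS4class{MSAGallery}.
#' @param palette see \code{\link{defaultPalette}}.
#' @param drawLabels rasterize the file-name labels.
#' @return numeric raster array.
#' @export
renderGallery <- function(gallery, palette = defaultPalette(),
                          drawLabels = TRUE) {
  img <- blankCanvas(gallery@height, gallery@width, palette)
  b <- gallery@blocks
  for (j in seq_len(nrow(b))) {
    rows <- gallery@rows[[j]]
    for (r in seq_along(rows)) {
      ch <- chars(rows[r])
      img <- paintPixels(img, b$x[j] + seq_along(ch) - 1,
                         rep(b$y[j] + r - 1, length(ch)),
                         paletteLookup(palette, ch))
    }
    if (drawLabels)
      img <- drawLabel(img, b$name[j],
                       c(b$x[j], max(0, b$y[j] - gallery@labelHeight),
                         b$x[j] + max(b$width[j], 40) - 1, b$y[j] - 1),
                       anchor = "top", opacity = 1, size = 8)
  }
  img
}
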