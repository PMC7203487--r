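#' Default nucleotide palette
#'
#' Colorblind-safe (Okabe-Ito) defaults in which greens and blues
#' predominate, G being the single warm hue, so AT-rich vs GC-rich
#' sequence separates by temperature at low zoom: A green (0,158,115),
#' C blue (0,114,178), T sky-blue (86,180,233), G orange (230,159,0),
#' N neutral gray (220,220,220), '-'/X and background white.  Lookup is
#' case-insensitive unless soft-mask dimming is enabled at render time.
#'
#' @param overrides optional named list of RGB triples (0-255) replacing
#'   individual entries, e.g. \code{list(G = c(200,0,0))}.
#' @return named list of RGB triples with a \code{background} entry.
#' @export
defaultPalette <- function(overrides = NULL) {
  pal <- list(
    A = c(0, 158, 115), C = c(0, 114, 178), T = c(86, 180, 233),
    G = c(230, 159, 0), U = c(86, 180, 233),
    N = c(220, 220, 220), X = c(255, 255, 255), `-` = c(255, 255, 255),
    background = c(255, 255, 255))
  for (nm in names(overrides)) pal[[nm]] <- overrides[[nm]]
  pal
}

## palette -> color matrix (3 x n) for a character vector, 0..1 scale;
## unknown characters fall back to N's color; lowercase optionally dimmed
## toward the background to show soft-masking
paletteLookup <- function(palette, ch, maskDim = FALSE) {
  up <- toupper(ch)
  known <- up %in% names(palette)
  up[!known] <- "N"
  m <- vapply(palette[up], identity, numeric(3)) / 255
  if (maskDim) {
    soft <- ch != up & known
    if (any(soft)) {
      bg <- palette$background / 255
      m[, soft] <- 0.55 * m[, soft] + 0.45 * bg
    }
  }
  m
}

## blank canvas h x w x 3 filled with the background color
blankCanvas <- function(h, w, palette) {
  bg <- palette$background / 255
  array(rep(bg, each = h * w), dim = c(h, w, 3))
}

## paint colors (3 x n matrix) at 0-based pixel coordinates
paintPixels <- function(img, x, y, colors) {
  h <- dim(img)[1]; w <- dim(img)[2]
  keep <- x >= 0 & x < w & y >= 0 & y < h
  lin <- (y[keep] + 1) + x[keep] * h          # [row, col] linear index
  img[lin] <- colors[1, keep]
  img[lin + h * w] <- colors[2, keep]
  img[lin + 2 * h * w] <- colors[3, keep]
  img
}

#' Render placed sequence to a raster
#'
#' Paints every placed base at its layout pixel; whitespace stays
#' background.  The canvas is sized to the bounding box of all drawn
#' pixels plus \code{margin}.  For a \linkS4class{PeanoLayout} with
#' \code{scale > 1} the path between consecutive bases is traced in
#' neutral gray.
#'
#' @param map a \linkS4class{ContigMap} (tile layouts).  For a
#'   \code{PeanoLayout} the contigs are threaded along the curve in
#'   order, ignoring column placement.
#' @param layout a \linkS4class{TileLayout} or \linkS4class{PeanoLayout}.
#' @param contigs sequences (\code{BStringSet} or named character).
#' @param palette see \code{\link{defaultPalette}}.
#' @param margin background pixels added on the right/bottom edges.
#' @param maskDim dim soft-masked (lowercase) bases toward background.
#' @return numeric array \code{[height, width, 3]} in [0, 1].
#' @export
renderRaster <- function(map, layout, contigs, palette = defaultPalette(),
                         margin = 0, maskDim = FALSE) {
  asChr <- function(nm) if (is.character(contigs)) contigs[[nm]]
                        else as.character(contigs[[nm]])
  e <- contigEntries(map)
  if (methods::is(layout, "PeanoLayout")) {
    seqAll <- paste(vapply(e$name, asChr, character(1)), collapse = "")
    return(renderPeano(seqAll, layout, palette, margin, maskDim))
  }
  total <- sum(e$length)
  if (total > capacity(layout))
    stopf("layout capacity %.0f < placed sequence %.0f",
          capacity(layout), total)
  if (total == 0) return(blankCanvas(1 + margin, 1 + margin, palette))
  xs <- vector("list", nrow(e)); ys <- xs; cols <- xs
  for (j in seq_len(nrow(e))) {
    idx <- e$start[j] + seq_len(e$length[j]) - 1
    p <- indexToPixel(layout, idx)
    xs[[j]] <- p$x; ys[[j]] <- p$y
    cols[[j]] <- paletteLookup(palette, chars(asChr(e$name[j])), maskDim)
  }
  x <- unlist(xs); y <- unlist(ys); col <- do.call(cbind, cols)
  img <- blankCanvas(max(y) + 1 + margin, max(x) + 1 + margin, palette)
  paintPixels(img, x, y, col)
}

## peano rendering of one concatenated sequence
renderPeano <- function(seq, layout, palette, margin = 0,
                        maskDim = FALSE) {
  L <- nchar(seq)
  if (L > capacity(layout))
    stopf("sequence (%d bases) exceeds the %.0f-cell grid; use larger radices",
          L, capacity(layout))
  dims <- peanoDims(layout)
  img <- blankCanvas(dims["height"] + margin, dims["width"] + margin,
                     palette)
  if (L == 0) return(img)
  idx <- seq_len(L) - 1
  p <- indexToPixel(layout, idx)
  s <- layout@scale
  if (s > 1 && L > 1) {                      # trace the path in gray
    gray <- matrix(rep(c(0.7, 0.7, 0.7), 1), nrow = 3)
    for (st in seq_len(s - 1)) {
      fx <- p$x[-L] + st * (p$x[-1] - p$x[-L]) / s
      fy <- p$y[-L] + st * (p$y[-1] - p$y[-L]) / s
      img <- paintPixels(img, round(fx), round(fy),
                         gray[, rep(1, L - 1), drop = FALSE])
    }
  }
  paintPixels(img, p$x, p$y, paletteLookup(palette, chars(seq), maskDim))
}

#' Write a raster as PNG
#'
#' @param img array from \code{\link{renderRaster}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeMasterPng <- function(img, path) {
  png::writePNG(img, path)
  invisible(path)
}

## area-average 2x downscale; odd trailing row/col replicated first so
## every output pixel is the mean of a full 2x2 block
halveImage <- function(img) {
  h <- dim(img)[1]; w <- dim(img)[2]
  if (h %% 2 == 1) img <- img[c(seq_len(h), h), , , drop = FALSE]
  if (w %% 2 == 1) img <- img[, c(seq_len(w), w), , drop = FALSE]
  h <- dim(img)[1]; w <- dim(img)[2]
  (img[seq(1, h, 2), seq(1, w, 2), , drop = FALSE] +
   img[seq(2, h, 2), seq(1, w, 2), , drop = FALSE] +
   img[seq(1, h, 2), seq(2, w, 2), , drop = FALSE] +
   img[seq(2, h, 2), seq(2, w, 2), , drop = FALSE]) / 4
}

#' Build a DeepZoom (DZI) image pyramid
#'
#' Writes \code{<name>.dzi} (Microsoft DeepZoom XML: Format png,
#' Overlap 0) and \code{<name>_files/<level>/<col>_<row>.png} tiles.
#' The top level index is \code{ceiling(log2(max dimension))}; each lower
#' level halves the image with area averaging (pixel colors merge as the
#' user zooms out), down to 1x1.
#'
#' @param img array from \code{\link{renderRaster}}.
#' @param dir output directory (created).
#' @param name basename for the descriptor and tile folder.
#' @param tileSize tile edge in pixels.
#' @return invisible list(dzi = path, levels = integer vector).
#' @export
buildPyramid <- function(img, dir, name = "master", tileSize = 256) {
  h <- dim(img)[1]; w <- dim(img)[2]
  top <- max(1, ceiling(log2(max(h, w))))
  filesDir <- file.path(dir, paste0(name, "_files"))
  dir.create(filesDir, recursive = TRUE, showWarnings = FALSE)
  cur <- img
  for (lev in seq(top, 0)) {
    levDir <- file.path(filesDir, lev)
    dir.create(levDir, showWarnings = FALSE)
    lh <- dim(cur)[1]; lw <- dim(cur)[2]
    nCols <- ceiling(lw / tileSize); nRows <- ceiling(lh / tileSize)
    for (tc in seq_len(nCols) - 1) for (tr in seq_len(nRows) - 1) {
      xi <- (tc * tileSize + 1):min((tc + 1) * tileSize, lw)
      yi <- (tr * tileSize + 1):min((tr + 1) * tileSize, lh)
      png::writePNG(cur[yi, xi, , drop = FALSE],
                    file.path(levDir, sprintf("%d_%d.png", tc, tr)))
    }
    if (lev > 0) cur <- halveImage(cur)
  }
  doc <- xml2::xml_new_root(
    "Image", xmlns = "http://schemas.microsoft.com/deepzoom/2008",
    Format = "png", Overlap = "0", TileSize = as.character(tileSize))
  xml2::xml_add_child(doc, "Size", Width = as.character(w),
                      Height = as.character(h))
  dziPath <- file.path(dir, paste0(name, ".dzi"))
  xml2::write_xml(doc, dziPath)
  invisible(list(dzi = dziPath, levels = seq(0, top)))
}

#' Font size and opacity for a label bounding box
#'
#' Monotone lookup keyed by bbox area (px^2): boxes under 1,000 px^2 get
#' no label; under 10,000 an 8 px opaque label; under 1,000,000 a 14 px
#' label at opacity 0.8; larger boxes a 28 px label at opacity 0.5 --
#' larger features get larger, more transparent labels.
#'
#' @param area bbox area in px^2 (vectorized).
#' @return data.frame(size, opacity); size 0 means skip.
#' @export
labelStyle <- function(area) {
  size <- ifelse(area < 1e3, 0, ifelse(area < 1e4, 8,
                 ifelse(area < 1e6, 14, 28)))
  opacity <- ifelse(area < 1e3, 0, ifelse(area < 1e4, 1.0,
                    ifelse(area < 1e6, 0.8, 0.5)))
  data.frame(size = size, opacity = opacity)
}

#' Draw a text label into a raster
#'
#' Rasterizes \code{text} with the built-in 5x7 bitmap font, scaled to
#' the requested size, alpha-blended at \code{opacity}, horizontally
#' centered in \code{bbox} and anchored to its top, bottom or center.
#' Labels that cannot fit the box at the smallest size are skipped with
#' a message.
#'
#' @param img raster array.
#' @param text label text (A-Z, a-z, 0-9 and basic punctuation).
#' @param bbox \code{c(x0, y0, x1, y1)} 0-based inclusive pixel box.
#' @param anchor one of \code{"top"}, \code{"bottom"}, \code{"centroid"}.
#' @param opacity alpha in [0, 1]; NULL picks from \code{labelStyle}.
#' @param size glyph height in px; NULL picks from \code{labelStyle}.
#' @param color RGB triple (0-255), default near-black.
#' @return the raster with the label drawn (unchanged if skipped).
#' @export
drawLabel <- function(img, text, bbox,
                      anchor = c("top", "bottom", "centroid"),
                      opacity = NULL, size = NULL, color = c(20, 20, 20)) {
  anchor <- match.arg(anchor)
  bw <- bbox[3] - bbox[1] + 1; bh <- bbox[4] - bbox[2] + 1
  sty <- labelStyle(bw * bh)
  if (is.null(size)) size <- sty$size
  if (is.null(opacity)) opacity <- sty$opacity
  if (size <= 0) {
    message(sprintf("label '%s': bbox %dx%d too small; skipped", text, bw, bh))
    return(img)
  }
  scale <- max(1, floor(size / 7))
  glyphs <- fontGlyphs()
  txt <- chars(text)
  txt[!txt %in% names(glyphs)] <- "."
  tw <- length(txt) * 6 * scale - scale
  th <- 7 * scale
  while (scale > 1 && (tw > bw || th > bh)) {
    scale <- scale - 1
    tw <- length(txt) * 6 * scale - scale; th <- 7 * scale
  }
  if (tw > bw || th > bh) {
    message(sprintf("label '%s': does not fit %dx%d bbox; skipped",
                    text, bw, bh))
    return(img)
  }
  x0 <- bbox[1] + floor((bw - tw) / 2)
  y0 <- switch(anchor, top = bbox[2], bottom = bbox[4] - th + 1,
               centroid = bbox[2] + floor((bh - th) / 2))
  h <- dim(img)[1]; w <- dim(img)[2]
  rgb <- color / 255
  for (ci in seq_along(txt)) {
    bits <- glyphs[[txt[ci]]]               # 5 column bytes, bit k = row k
    for (col in 0:4) for (row in 0:6) {
      if (bitwAnd(bits[col + 1], bitwShiftL(1, row)) == 0) next
      px <- x0 + (ci - 1) * 6 * scale + col * scale + seq_len(scale) - 1
      py <- y0 + row * scale + seq_len(scale) - 1
      for (xx in px) for (yy in py) {
        if (xx < 0 || xx >= w || yy < 0 || yy >= h) next
        img[yy + 1, xx + 1, ] <- (1 - opacity) * img[yy + 1, xx + 1, ] +
          opacity * rgb
      }
    }
  }
  img
}

## classic 5x7 column-byte font (subset); bit k of a column = row k (top=0)
fontGlyphs <- function() {
  g <- list(
    A = c(0x7C, 0x12, 0x11, 0x12, 0x7C), B = c(0x7F, 0x49, 0x49, 0x49, 0x36),
    C = c(0x3E, 0x41, 0x41, 0x41, 0x22), D = c(0x7F, 0x41, 0x41, 0x22, 0x1C),
    E = c(0x7F, 0x49, 0x49, 0x49, 0x41), F = c(0x7F, 0x09, 0x09, 0x09, 0x01),
    G = c(0x3E, 0x41, 0x49, 0x49, 0x7A), H = c(0x7F, 0x08, 0x08, 0x08, 0x7F),
    I = c(0x00, 0x41, 0x7F, 0x41, 0x00), J = c(0x20, 0x40, 0x41, 0x3F, 0x01),
    K = c(0x7F, 0x08, 0x14, 0x22, 0x41), L = c(0x7F, 0x40, 0x40, 0x40, 0x40),
    M = c(0x7F, 0x02, 0x0C, 0x02, 0x7F), N = c(0x7F, 0x04, 0x08, 0x10, 0x7F),
    O = c(0x3E, 0x41, 0x41, 0x41, 0x3E), P = c(0x7F, 0x09, 0x09, 0x09, 0x06),
    Q = c(0x3E, 0x41, 0x51, 0x21, 0x5E), R = c(0x7F, 0x09, 0x19, 0x29, 0x46),
    S = c(0x46, 0x49, 0x49, 0x49, 0x31), T = c(0x01, 0x01, 0x7F, 0x01, 0x01),
    U = c(0x3F, 0x40, 0x40, 0x40, 0x3F), V = c(0x1F, 0x20, 0x40, 0x20, 0x1F),
    W = c(0x3F, 0x40, 0x38, 0x40, 0x3F), X = c(0x63, 0x14, 0x08, 0x14, 0x63),
    Y = c(0x07, 0x08, 0x70, 0x08, 0x07), Z = c(0x61, 0x51, 0x49, 0x45, 0x43),
    `0` = c(0x3E, 0x51, 0x49, 0x45, 0x3E), `1` = c(0x00, 0x42, 0x7F, 0x40, 0x00),
    `2` = c(0x42, 0x61, 0x51, 0x49, 0x46), `3` = c(0x21, 0x41, 0x45, 0x4B, 0x31),
    `4` = c(0x18, 0x14, 0x12, 0x7F, 0x10), `5` = c(0x27, 0x45, 0x45, 0x45, 0x39),
    `6` = c(0x3C, 0x4A, 0x49, 0x49, 0x30), `7` = c(0x01, 0x71, 0x09, 0x05, 0x03),
    `8` = c(0x36, 0x49, 0x49, 0x49, 0x36), `9` = c(0x06, 0x49, 0x49, 0x29, 0x1E),
    ` ` = c(0x00, 0x00, 0x00, 0x00, 0x00), `.` = c(0x00, 0x60, 0x60, 0x00, 0x00),
    `-` = c(0x08, 0x08, 0x08, 0x08, 0x08), `_` = c(0x40, 0x40, 0x40, 0x40, 0x40),
    `:` = c(0x00, 0x36, 0x36, 0x00, 0x00), `/` = c(0x20, 0x10, 0x08, 0x04, 0x02),
    `+` = c(0x08, 0x08, 0x3E, 0x08, 0x08), `(` = c(0x00, 0x1C, 0x22, 0x41, 0x00),
    `)` = c(0x00, 0x41, 0x22, 0x1C, 0x00))
  c(g, stats::setNames(g[toupper(letters)], letters))  # lowercase = uppercase

}
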