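annPriority <- c(none = 0L, gene = 1L, mRNA = 2L, exon = 3L, CDS = 4L)
annLevels <- names(annPriority)

#' Flatten features to a per-base annotation code array
#'
#' Each placed base receives the highest-priority feature type covering
#' it, in the order CDS > exon > mRNA > gene (only one annotation type
#' can be shown per base in the parallel track).  Repeat features
#' (\code{type} containing "repeat", or all features when
#' \code{role = "repeat"}) go to a separate parallel logical array.
#'
#' @param features \code{GRanges} from \code{\link{readAnnotations}}.
#' @param map a \linkS4class{ContigMap}; feature seqnames must match
#'   placed contig names.
#' @param role \code{"ref"} (default) or \code{"repeat"}.
#' @return list(codes = factor vector over the placed index space with
#'   levels none/gene/mRNA/exon/CDS, repeats = logical vector,
#'   offsets = named vector mapping contig name to position of its first
#'   base in the arrays).
#' @export
flattenFeatures <- function(features, map, role = c("ref", "repeat")) {
  role <- match.arg(role)
  e <- contigEntries(map)
  seqids <- unique(as.character(GenomicRanges::seqnames(features)))
  missing <- setdiff(seqids, e$name)
  if (length(missing))
    stopf("feature seqid(s) not among placed contigs: %s",
          paste(missing, collapse = ", "))
  total <- sum(e$length)
  codes <- integer(total)                     # 0 = none
  repeats <- logical(total)
  offsets <- stats::setNames(cumsum(c(0, e$length[-nrow(e)])), e$name)
  ft <- as.character(S4Vectors::mcols(features)$ftype)
  isRep <- role == "repeat" |
    grepl("repeat", as.character(S4Vectors::mcols(features)$type),
          ignore.case = TRUE)
  pr <- annPriority[ft]
  pr[is.na(pr)] <- 0L                         # 'other' features: no code
  st <- GenomicRanges::start(features); en <- GenomicRanges::end(features)
  sq <- as.character(GenomicRanges::seqnames(features))
  for (j in seq_along(features)) {
    clen <- e$length[match(sq[j], e$name)]
    lo <- max(1, st[j]); hi <- min(en[j], clen)
    if (hi < lo) next
    span <- offsets[[sq[j]]] + lo:hi
    if (isRep[j]) repeats[span] <- TRUE
    if (pr[j] > 0) codes[span] <- pmax(codes[span], pr[j])
  }
  list(codes = factor(annLevels[codes + 1L], levels = annLevels),
       repeats = repeats, offsets = offsets)
}

## pixels of a contiguous per-base span (1-based positions within the
## placed array) under a layout + map
spanPixels <- function(map, layout, positions) {
  e <- contigEntries(map)
  offsets <- cumsum(c(0, e$length[-nrow(e)]))
  glb <- numeric(length(positions))
  for (j in seq_len(nrow(e))) {
    inC <- positions > offsets[j] & positions <= offsets[j] + e$length[j]
    glb[inC] <- e$start[j] + (positions[inC] - offsets[j] - 1)
  }
  indexToPixel(layout, glb)
}

## alpha-blend given (0-based) pixels toward a target color
blendPixels <- function(img, x, y, alpha, target = c(1, 1, 1)) {
  h <- dim(img)[1]; w <- dim(img)[2]
  keep <- x >= 0 & x < w & y >= 0 & y < h
  lin <- (y[keep] + 1) + x[keep] * h
  for (k in 1:3) {
    off <- (k - 1) * h * w
    img[lin + off] <- (1 - alpha) * img[lin + off] + alpha * target[k]
  }
  img
}

#' Overlay annotation highlights on a sequence raster
#'
#' \code{role = "ref"}: gene bodies are lightened toward white, introns
#' at alpha 0.2 and exons/CDS at alpha 0.45, one blend per feature, so
#' overlapping annotations show as doubly highlighted areas.
#' \code{role = "repeat"}: covered pixels are darkened toward black at
#' alpha 0.35.  \code{role = "query"}: a 2 px drop shadow is drawn
#' around each feature's bounding box; where the shadow would collide
#' with other annotated pixels it is shifted inward by the overlap
#' (set-intersection test) and the adjustment is reported.
#'
#' @param img raster from \code{\link{renderRaster}} (same layout!).
#' @param layout the layout used to render \code{img}.
#' @param map the \linkS4class{ContigMap} used to render \code{img}.
#' @param features \code{GRanges} annotations.
#' @param role one of \code{"ref"}, \code{"query"}, \code{"repeat"}.
#' @param alphas blending constants (intron, exon, repeat).
#' @return the annotated raster.
#' @export
overlayHighlights <- function(img, layout, map, features,
                              role = c("ref", "query", "repeat"),
                              alphas = c(intron = 0.2, exon = 0.45,
                                         repeat_ = 0.35)) {
  role <- match.arg(role)
  e <- contigEntries(map)
  offsets <- stats::setNames(cumsum(c(0, e$length[-nrow(e)])), e$name)
  ft <- as.character(S4Vectors::mcols(features)$ftype)
  sq <- as.character(GenomicRanges::seqnames(features))
  st <- GenomicRanges::start(features); en <- GenomicRanges::end(features)

  featPositions <- function(j) {
    clen <- e$length[match(sq[j], e$name)]
    lo <- max(1, st[j]); hi <- min(en[j], clen)
    if (hi < lo) return(integer())
    offsets[[sq[j]]] + lo:hi
  }

  if (role == "ref") {
    genes <- which(ft == "gene")
    exonic <- which(ft %in% c("exon", "CDS"))
    for (j in genes) {
      pos <- featPositions(j)
      if (!length(pos)) next
      exMask <- rep(FALSE, length(pos))
      for (k in exonic) {
        if (sq[k] != sq[j]) next
        hit <- pos >= offsets[[sq[j]]] + st[k] & pos <= offsets[[sq[j]]] + en[k]
        exMask <- exMask | hit
      }
      p <- spanPixels(map, layout, pos)
      img <- blendPixels(img, p$x[!exMask], p$y[!exMask], alphas[["intron"]])
      img <- blendPixels(img, p$x[exMask], p$y[exMask], alphas[["exon"]])
    }
  } else if (role == "repeat") {
    for (j in seq_along(features)) {
      pos <- featPositions(j)
      if (!length(pos)) next
      p <- spanPixels(map, layout, pos)
      img <- blendPixels(img, p$x, p$y, alphas[["repeat_"]],
                         target = c(0, 0, 0))
    }
  } else {                                   # query: drop shadows
    annPix <- new.env(parent = emptyenv())    # occupied pixel set
    markAnn <- function(p) for (i in seq_along(p$x))
      assign(paste0(p$x[i], ",", p$y[i]), TRUE, annPix)
    for (j in seq_along(features)) markAnn(spanPixels(map, layout,
                                                      featPositions(j)))
    for (j in seq_along(features)) {
      p <- spanPixels(map, layout, featPositions(j))
      if (!length(p$x)) next
      bx0 <- min(p$x); bx1 <- max(p$x); by0 <- min(p$y); by1 <- max(p$y)
      for (d in 1:2) {                       # 2 px shadow ring
        ring <- rbind(
          cbind(x = (bx0 - d):(bx1 + d), y = by0 - d),
          cbind(x = (bx0 - d):(bx1 + d), y = by1 + d),
          cbind(x = bx0 - d, y = (by0 - d + 1):(by1 + d - 1)),
          cbind(x = bx1 + d, y = (by0 - d + 1):(by1 + d - 1)))
        collide <- vapply(seq_len(nrow(ring)), function(i)
          exists(paste0(ring[i, 1], ",", ring[i, 2]), annPix), logical(1))
        if (any(collide)) {
          message(sprintf(
            "drop shadow for feature %d: %d px collide; shifted inward",
            j, sum(collide)))
          ring[collide, 1] <- pmin(pmax(ring[collide, 1], bx0), bx1)
          ring[collide, 2] <- pmin(pmax(ring[collide, 2], by0), by1)
        }
        img <- blendPixels(img, ring[, 1], ring[, 2], 0.3,
                           target = c(0, 0, 0))
      }
    }
  }
  img
}

#' Annotation track colors
#'
#' @return named list of RGB triples: introns/mRNA orange, exons blue,
#'   CDS red, gene (no finer structure) orange, none white.
#' @export
annotationTrackColors <- function() list(
  none = c(255, 255, 255), gene = c(255, 165, 0), mRNA = c(255, 165, 0),
  exon = c(0, 90, 200), CDS = c(220, 30, 30))

#' Render the parallel annotation track interlaced with sequence columns
#'
#' The annotation pseudosequence (one code per base, priority CDS > exon
#' > mRNA > gene) is rendered in columns of \code{annotationWidth} pixels
#' placed left of each sequence column; each track row compresses the
#' row's bases into \code{annotationWidth} bins colored by the
#' highest-priority code in the bin.  Feature labels go to the column
#' containing the feature's median base.
#'
#' @param img sequence raster from \code{\link{renderRaster}}.
#' @param layout the \linkS4class{TileLayout} used for \code{img}.
#' @param map the \linkS4class{ContigMap} used for \code{img}.
#' @param features \code{GRanges} annotations.
#' @param annotationWidth track width in pixels (>= 1).
#' @param gap background pixels between track and sequence column.
#' @param drawLabels rasterize gene labels onto the track columns.
#' @return a wider raster with interlaced annotation columns.
#' @export
buildAnnotationTrack <- function(img, layout, map, features,
                                 annotationWidth = 4, gap = 1,
                                 drawLabels = TRUE) {
  stopifnot(annotationWidth >= 1)
  flat <- flattenFeatures(features, map)
  codes <- as.integer(flat$codes) - 1L       # 0 none .. 4 CDS
  e <- contigEntries(map)
  rowW <- layout@radices[1]
  colCap <- rowW * layout@radices[2]
  h <- dim(img)[1]; w <- dim(img)[2]
  ins <- annotationWidth + gap
  ## occupied columns (global column numbers) and their unshifted x
  colNums <- sort(unique(unlist(lapply(seq_len(nrow(e)), function(j) {
    seq.int(e$start[j] %/% colCap, (e$start[j] + e$length[j] - 1) %/% colCap)
  }))))
  colStartX <- indexToPixel(layout, colNums * colCap)$x
  out <- blankCanvas(h, w + length(colStartX) * ins, defaultPalette())
  ## copy each sequence column strip right by (rank * ins); the strip of
  ## column rank ci runs to just before the next column's start
  for (ci in seq_along(colStartX)) {
    x0 <- colStartX[ci]
    x1 <- if (ci < length(colStartX)) colStartX[ci + 1] - 1 else w - 1
    out[, (x0 + ci * ins + 1):(x1 + ci * ins + 1), ] <-
      img[, (x0 + 1):(x1 + 1), , drop = FALSE]
  }
  ## paint track bins: per row, annotationWidth bins each covering
  ## rowW/annotationWidth bases, colored by the max-priority code
  pal <- vapply(annotationTrackColors(), identity, numeric(3)) / 255
  offsets <- cumsum(c(0, e$length[-nrow(e)]))
  binW <- rowW / annotationWidth
  for (j in seq_len(nrow(e))) {
    len <- e$length[j]
    idx <- e$start[j] + seq_len(len) - 1
    p <- indexToPixel(layout, idx)
    rank <- findInterval(idx %/% colCap, colNums)
    trackX <- colStartX[rank] + (rank - 1) * ins +
      pmin((idx %% rowW) %/% binW, annotationWidth - 1)
    codeHere <- codes[offsets[j] + seq_len(len)]
    agg <- tapply(codeHere, paste0(trackX, "_", p$y), max)
    xy <- do.call(rbind, strsplit(names(agg), "_", fixed = TRUE))
    out <- paintPixels(out, as.numeric(xy[, 1]), as.numeric(xy[, 2]),
                       pal[, annLevels[agg + 1L], drop = FALSE])
  }
  ## labels at the median column of each gene
  if (drawLabels) {
    ft <- as.character(S4Vectors::mcols(features)$ftype)
    lab <- as.character(S4Vectors::mcols(features)$label)
    sq <- as.character(GenomicRanges::seqnames(features))
    for (jf in which(ft == "gene" & nzchar(lab))) {
      je <- match(sq[jf], e$name)
      if (is.na(je)) next
      span <- GenomicRanges::start(features)[jf]:
              min(GenomicRanges::end(features)[jf], e$length[je])
      gidx <- e$start[je] + span - 1
      covered <- sort(unique(gidx %/% colCap))
      medCol <- covered[ceiling(length(covered) / 2)]
      rank <- findInterval(medCol, colNums)
      inCol <- gidx %/% colCap == medCol
      py <- indexToPixel(layout, gidx[inCol])$y
      x0 <- colStartX[rank] + rank * ins     # shifted sequence column start
      out <- drawLabel(out, lab[jf],
                       c(x0, min(py), x0 + rowW - 1, max(max(py), min(py) + 8)),
                       anchor = "top", opacity = 0.9, size = 8)
    }
  }
  out
}

#' @describeIn buildAnnotationTrack the column (global column number) a
#'   feature's label lands in: the column containing the feature's
#'   median covered column.
#' @param colCap bases per column of the layout in use.
#' @param startIdx,endIdx inclusive global layout index range of the
#'   feature.
#' @export
labelColumnOf <- function(startIdx, endIdx, colCap) {
  covered <- seq.int(startIdx %/% colCap, endIdx %/% colCap)
  covered[ceiling(length(covered) / 2)]
}

#' Compute label placements for annotated features
#'
#' Tile layouts: the label bbox is the rectangle of the feature's first
#' column segment; genes on the positive strand anchor their label at the
#' top of the box, negative-strand genes at the bottom.  Ideogram
#' (Peano) layouts: the label is placed at the geometric centroid of the
#' feature's mapped pixels, with a bbox from their min/max coordinates.
#' Size and opacity come from the monotone area lookup
#' (\code{\link{labelStyle}}): larger features get larger, more
#' transparent labels.
#'
#' @param features \code{GRanges} annotations (genes are labeled).
#' @param map a \linkS4class{ContigMap}.
#' @param layout the layout in use.
#' @return data.frame(text, x0, y0, x1, y1, anchor, size, opacity).
#' @export
placeLabels <- function(features, map, layout) {
  e <- contigEntries(map)
  offsets <- stats::setNames(cumsum(c(0, e$length[-nrow(e)])), e$name)
  ft <- as.character(S4Vectors::mcols(features)$ftype)
  lab <- as.character(S4Vectors::mcols(features)$label)
  sq <- as.character(GenomicRanges::seqnames(features))
  strand <- as.character(GenomicRanges::strand(features))
  ideogram <- methods::is(layout, "PeanoLayout")
  rows <- list()
  for (j in which(ft == "gene" & nzchar(lab))) {
    je <- match(sq[j], e$name)
    if (is.na(je)) next
    span <- max(1, GenomicRanges::start(features)[j]):
            min(GenomicRanges::end(features)[j], e$length[je])
    p <- spanPixels(map, layout, offsets[[sq[j]]] + span)
    if (ideogram) {
      cx <- mean(p$x); cy <- mean(p$y)
      x0 <- min(p$x); x1 <- max(p$x); y0 <- min(p$y); y1 <- max(p$y)
      anchor <- "centroid"
      bbox <- c(x0, y0, x1, y1)
      centroid <- c(cx, cy)
    } else {
      firstColX <- p$x[1]
      sameCol <- abs(p$x - firstColX) < layout@radices[1]
      bbox <- c(min(p$x[sameCol]), min(p$y[sameCol]),
                min(p$x[sameCol]) + layout@radices[1] - 1,
                max(p$y[sameCol]))
      anchor <- if (strand[j] == "-") "bottom" else "top"
      centroid <- c(mean(bbox[c(1, 3)]), mean(bbox[c(2, 4)]))
    }
    area <- (bbox[3] - bbox[1] + 1) * (bbox[4] - bbox[2] + 1)
    sty <- labelStyle(area)
    rows[[length(rows) + 1]] <- data.frame(
      text = lab[j], x0 = bbox[1], y0 = bbox[2], x1 = bbox[3],
      y1 = bbox[4], anchor = anchor, size = sty$size,
      opacity = sty$opacity, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(text = character(), x0 = numeric(), y0 = numeric(),
                      x1 = numeric(), y1 = numeric(), anchor = character(),
                      size = numeric(), opacity = numeric()))
  do.call(rbind, rows)
}
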