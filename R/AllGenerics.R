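#' @rdname tileLayout
#' @param x a layout object.
#' @export
setGeneric("capacity", function(x) standardGeneric("capacity"))

#' Map sequence indices to pixel coordinates
#'
#' Exact forward transform of a layout.  For a \linkS4class{TileLayout}
#' the mixed-radix digits of the 0-based index are multiplied by the
#' per-level strides and summed per axis; for a
#' \linkS4class{PeanoLayout} the index is threaded along the space-filling
#' curve and multiplied by the drawing scale.  Vectorized over \code{i}.
#'
#' @param layout a \linkS4class{TileLayout} or \linkS4class{PeanoLayout}.
#' @param i 0-based sequence index (vector allowed).
#' @return data.frame with columns \code{x}, \code{y} (0-based pixels).
#' @export
setGeneric("indexToPixel", function(layout, i) standardGeneric("indexToPixel"))

#' Map pixel coordinates back to sequence indices
#'
#' Exact inverse of \code{\link{indexToPixel}} on drawable pixels; pixels
#' that fall in padding/whitespace or outside the canvas give \code{NA}.
#' Vectorized over \code{x}, \code{y}.
#'
#' @param layout a \linkS4class{TileLayout} or \linkS4class{PeanoLayout}.
#' @param x,y 0-based pixel coordinates (vectors of equal length).
#' @return numeric vector of 0-based indices with \code{NA} for
#'   whitespace/out-of-canvas pixels.
#' @export
setGeneric("pixelToIndex", function(layout, x, y) standardGeneric("pixelToIndex"))
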