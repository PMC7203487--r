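#' Construct a Peano space-filling curve layout
#'
#' The ideogram layout threads the sequence along a generalized Peano
#' curve: at each level an \code{a x b} grid of sub-blocks is traversed in
#' boustrophedon (serpentine) order, columns alternating up/down, with
#' alternate sub-blocks mirrored so the exit cell of one block is
#' grid-adjacent to the entry cell of the next.  With odd radices the
#' whole path is continuous: consecutive sequence positions are always
#' unit grid neighbors, and locality is preserved at every level of the
#' recursion.
#'
#' @param xRadices odd integers, coarse to fine, along x.
#' @param yRadices odd integers, same length, along y.
#' @param scale integer >= 1; drawing magnification (see
#'   \linkS4class{PeanoLayout}).
#' @return A \linkS4class{PeanoLayout}.
#' @examples
#' pl <- peanoLayout(c(3, 3, 3), c(5, 3, 3))   # 27 x 45 grid, 1215 cells
#' capacity(pl)
#' @export
peanoLayout <- function(xRadices = c(3, 3, 3), yRadices = c(5, 3, 3),
                        scale = 1) {
  obj <- new("PeanoLayout", xRadices = as.numeric(xRadices),
             yRadices = as.numeric(yRadices), scale = as.numeric(scale))
  validObject(obj)
  obj
}

#' @rdname peanoLayout
#' @param x a \code{PeanoLayout}.
#' @export
setMethod("capacity", "PeanoLayout", function(x)
  prod(x@xRadices) * prod(x@yRadices))

#' @describeIn peanoLayout grid (and drawn, = grid * scale) dimensions.
#' @param layout a \code{PeanoLayout}.
#' @export
peanoDims <- function(layout) {
  c(width = prod(layout@xRadices) * layout@scale,
    height = prod(layout@yRadices) * layout@scale)
}

setMethod("show", "PeanoLayout", function(object) {
  cat("PeanoLayout: x radices (", paste(object@xRadices, collapse = ","),
      "), y radices (", paste(object@yRadices, collapse = ","),
      "), scale ", object@scale, "\n", sep = "")
  cat("  grid ", prod(object@xRadices), " x ", prod(object@yRadices),
      " = ", capacity(object), " cells\n", sep = "")
})

## Forward map on the unscaled cell grid, vectorized over i.
## At each level, block visit order k is decomposed into a serpentine
## (column bx, position kk within the column); the accumulated mirror
## state (rx, ry) reflects the block position, and the level's own
## mirroring (x: odd kk, y: odd bx) is composed into the state for the
## finer levels.  Induction: every sub-path runs corner to opposite
## corner, so mirrored entries/exits line up and the path is continuous.
peanoCellForward <- function(layout, i) {
  xr <- layout@xRadices; yr <- layout@yRadices
  n <- length(xr)
  cellsBelow <- rev(cumprod(rev(xr * yr)))           # per level incl. own
  cellsBelow <- c(cellsBelow[-1], 1)                 # cells per sub-block
  blockW <- c(rev(cumprod(rev(xr)))[-1], 1)          # sub-block width
  blockH <- c(rev(cumprod(rev(yr)))[-1], 1)
  X <- numeric(length(i)); Y <- numeric(length(i))
  rx <- logical(length(i)); ry <- logical(length(i))
  rem <- i
  for (l in seq_len(n)) {
    a <- xr[l]; b <- yr[l]
    k <- rem %/% cellsBelow[l]
    rem <- rem %% cellsBelow[l]
    bx <- k %/% b
    kk <- k %% b
    by <- ifelse(bx %% 2 == 0, kk, b - 1 - kk)
    nrx <- kk %% 2 == 1
    nry <- bx %% 2 == 1
    bx <- ifelse(rx, a - 1 - bx, bx)
    by <- ifelse(ry, b - 1 - by, by)
    X <- X + bx * blockW[l]
    Y <- Y + by * blockH[l]
    rx <- xor(rx, nrx)
    ry <- xor(ry, nry)
  }
  list(x = X, y = Y)
}

## Inverse on the unscaled cell grid, vectorized; NA when out of grid.
peanoCellInverse <- function(layout, cx, cy) {
  xr <- layout@xRadices; yr <- layout@yRadices
  n <- length(xr)
  cellsBelow <- rev(cumprod(rev(xr * yr)))
  cellsBelow <- c(cellsBelow[-1], 1)
  blockW <- c(rev(cumprod(rev(xr)))[-1], 1)
  blockH <- c(rev(cumprod(rev(yr)))[-1], 1)
  ok <- cx >= 0 & cy >= 0 & cx < prod(xr) & cy < prod(yr) &
        cx == floor(cx) & cy == floor(cy)
  idx <- numeric(length(cx))
  rx <- logical(length(cx)); ry <- logical(length(cx))
  for (l in seq_len(n)) {
    a <- xr[l]; b <- yr[l]
    bx <- cx %/% blockW[l]; cx <- cx %% blockW[l]
    by <- cy %/% blockH[l]; cy <- cy %% blockH[l]
    bx <- ifelse(rx, a - 1 - bx, bx)          # undo accumulated mirrors
    by <- ifelse(ry, b - 1 - by, by)
    kk <- ifelse(bx %% 2 == 0, by, b - 1 - by)
    k <- bx * b + kk
    idx <- idx + k * cellsBelow[l]
    rx <- xor(rx, kk %% 2 == 1)
    ry <- xor(ry, bx %% 2 == 1)
  }
  idx[!ok] <- NA_real_
  idx
}

#' @rdname indexToPixel
#' @export
setMethod("indexToPixel", "PeanoLayout", function(layout, i) {
  if (any(i < 0) || any(i >= capacity(layout)))
    stopf("index out of range [0, %.0f)", capacity(layout))
  p <- peanoCellForward(layout, i)
  data.frame(x = p$x * layout@scale, y = p$y * layout@scale)
})

#' @rdname pixelToIndex
#' @export
setMethod("pixelToIndex", "PeanoLayout", function(layout, x, y) {
  s <- layout@scale
  onCell <- x %% s == 0 & y %% s == 0
  idx <- peanoCellInverse(layout, x %/% s, y %/% s)
  idx[!onCell] <- NA_real_   # inter-cell whitespace when scale > 1
  idx
})
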