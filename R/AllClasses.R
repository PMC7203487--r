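#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
NULL

#' TileLayout: nested mixed-radix sequence-to-pixel map
#'
#' A \code{TileLayout} arranges a 1D sequence index space into nested 2D
#' tiles: level 0 lays bases along x (a row), level 1 stacks rows along y
#' (a column), level 2 places columns along x (a mega-row), and so on,
#' alternating axes.  Each level has a radix (how many sub-units it holds)
#' and a trailing padding in pixels (whitespace after each unit).  Strides
#' are derived: the stride of the first level on an axis is
#' \code{1 + padding}, and the stride of a later level on the same axis is
#' \code{radix_prev * stride_prev + padding}.
#'
#' @slot radices integer vector of per-level radices (level 0 = x).
#' @slot paddings integer vector, same length, trailing whitespace per unit.
#' @slot strides numeric vector of per-level pixel strides (derived).
#' @slot capacity numeric, product of radices (bases addressable).
#' @exportClass TileLayout
setClass("TileLayout", representation(
  radices = "numeric", paddings = "numeric",
  strides = "numeric", capacity = "numeric"
))

setValidity("TileLayout", function(object) {
  msgs <- character()
  if (length(object@radices) != length(object@paddings))
    msgs <- c(msgs, "radices and paddings must have equal length")
  if (length(object@radices) < 2)
    msgs <- c(msgs, "at least two levels (one x, one y) are required")
  if (length(object@radices) > 10)
    msgs <- c(msgs, "layouts with more than 10 levels are not supported")
  if (any(object@radices < 1)) msgs <- c(msgs, "all radices must be >= 1")
  if (any(object@paddings < 0)) msgs <- c(msgs, "paddings must be >= 0")
  if (!isTRUE(all.equal(object@capacity, prod(object@radices))))
    msgs <- c(msgs, "capacity must equal the product of the radices")
  if (length(msgs)) msgs else TRUE
})

#' PeanoLayout: continuous space-filling curve layout
#'
#' Defines a generalized Peano curve over a grid of
#' \code{prod(xRadices) x prod(yRadices)} cells.  All radices must be odd
#' (>= 3 recursion, or a single level >= 1): odd radices are what make the
#' boustrophedon recursion exit each block adjacent to the entry of the
#' next, so the full path is continuous (every step is one grid unit).
#' \code{scale} magnifies the drawing: each nucleotide is painted at
#' \code{(scale*x, scale*y)} and, when \code{scale > 1}, the pixels between
#' consecutive nucleotides are traced in neutral gray.
#'
#' @slot xRadices integer vector (coarse to fine) of x radices.
#' @slot yRadices integer vector, same length, of y radices.
#' @slot scale integer >= 1 drawing magnification.
#' @exportClass PeanoLayout
setClass("PeanoLayout", representation(
  xRadices = "numeric", yRadices = "numeric", scale = "numeric"
))

setValidity("PeanoLayout", function(object) {
  msgs <- character()
  if (length(object@xRadices) != length(object@yRadices))
    msgs <- c(msgs, "xRadices and yRadices must have equal length")
  if (length(object@xRadices) < 1) msgs <- c(msgs, "at least one level required")
  odd <- c(object@xRadices, object@yRadices) %% 2 == 1
  if (!all(odd))
    msgs <- c(msgs, paste0(
      "all radices must be odd: even radices break the continuity of the ",
      "curve (the serpentine exit cell would not be adjacent to the next entry)"))
  if (any(c(object@xRadices, object@yRadices) < 1))
    msgs <- c(msgs, "radices must be positive")
  if (length(object@scale) != 1 || object@scale < 1)
    msgs <- c(msgs, "scale must be a single integer >= 1")
  if (length(msgs)) msgs else TRUE
})

#' ContigMap: placement of contigs in layout index space
#'
#' Ordered assignment of each contig to a contiguous 0-based index range in
#' a layout's address space.  Ranges are disjoint and ascending; each
#' contig starts at a column boundary (and at a mega-column boundary when
#' it would not fit in the remainder of the current mega-column).
#'
#' @slot entries data.frame with columns \code{name}, \code{start}
#'   (0-based global layout index) and \code{length}.
#' @exportClass ContigMap
setClass("ContigMap", representation(entries = "data.frame"))

setValidity("ContigMap", function(object) {
  e <- object@entries
  need <- c("name", "start", "length")
  if (!all(need %in% names(e))) return("entries needs name/start/length")
  if (nrow(e) > 1) {
    ends <- e$start + e$length
    if (any(e$start[-1] < ends[-nrow(e)]))
      return("contig index ranges must be disjoint and ascending")
  }
  TRUE
})

#' Chain: one UCSC liftOver chain
#'
#' A scored chain of gapless aligned blocks between a target (reference)
#' and query sequence.  Coordinates are 0-based half-open as in the chain
#' format; query coordinates of a '-' strand chain are on the
#' reverse-complemented query.  \code{blocks} has columns \code{size},
#' \code{dt} (unaligned target bases after the block) and \code{dq}
#' (unaligned query bases after the block); the last block has dt = dq = 0.
#'
#' @slot score numeric chain score.
#' @slot tName,tSize,tStart,tEnd target (reference) name/size/interval.
#' @slot tStrand always "+".
#' @slot qName,qSize,qStart,qEnd,qStrand query side; strand "+" or "-".
#' @slot chainId integer chain id.
#' @slot blocks data.frame(size, dt, dq).
#' @exportClass Chain
setClass("Chain", representation(
  score = "numeric",
  tName = "character", tSize = "numeric", tStrand = "character",
  tStart = "numeric", tEnd = "numeric",
  qName = "character", qSize = "numeric", qStrand = "character",
  qStart = "numeric", qEnd = "numeric",
  chainId = "numeric", blocks = "data.frame"
))

setValidity("Chain", function(object) {
  b <- object@blocks
  msgs <- character()
  if (object@tStrand != "+") msgs <- c(msgs, "tStrand must be '+'")
  if (!object@qStrand %in% c("+", "-")) msgs <- c(msgs, "qStrand must be +/-")
  if (nrow(b)) {
    if (any(b$size < 1)) msgs <- c(msgs, "block sizes must be >= 1")
    if (any(b$dt < 0) || any(b$dq < 0)) msgs <- c(msgs, "gaps must be >= 0")
    if (b$dt[nrow(b)] != 0 || b$dq[nrow(b)] != 0)
      msgs <- c(msgs, "last block must have dt = dq = 0")
    if (sum(b$size + b$dt) != object@tEnd - object@tStart)
      msgs <- c(msgs, sprintf(
        "chain %d: sum(size+dt)=%d != tEnd-tStart=%d", object@chainId,
        sum(b$size + b$dt), object@tEnd - object@tStart))
    if (sum(b$size + b$dq) != object@qEnd - object@qStart)
      msgs <- c(msgs, sprintf(
        "chain %d: sum(size+dq)=%d != qEnd-qStart=%d", object@chainId,
        sum(b$size + b$dq), object@qEnd - object@qStart))
  }
  if (length(msgs)) msgs else TRUE
})

#' CompositeAlignment: linearized whole-genome alignment
#'
#' The gapped reference/query pseudosequence pair produced by compositing
#' all chains of a liftOver file onto one reference chromosome, plus
#' per-base provenance.  Provenance intervals partition the gapped length;
#' classes are \code{syntenic} (master chain), \code{intra} (secondary
#' chain, same query chromosome as master), \code{inter} (different query
#' chromosome), \code{unaligned_ref} (reference-only sequence) and
#' \code{unaligned_query} (query-only sequence pulled in at master-chain
#' dq gaps).
#'
#' @slot refGapped,queryGapped equal-length character strings over
#'   bases plus '-'.
#' @slot provenance data.frame(start, end, class, chainId, qName, qStrand)
#'   with 0-based half-open intervals on the gapped coordinate.
#' @slot refName name of the reference contig.
#' @exportClass CompositeAlignment
setClass("CompositeAlignment", representation(
  refGapped = "character", queryGapped = "character",
  provenance = "data.frame", refName = "character"
))

setValidity("CompositeAlignment", function(object) {
  msgs <- character()
  if (nchar(object@refGapped) != nchar(object@queryGapped))
    msgs <- c(msgs, "gapped sequences must have equal length")
  p <- object@provenance
  if (nrow(p)) {
    if (p$start[1] != 0 || p$end[nrow(p)] != nchar(object@refGapped) ||
        (nrow(p) > 1 && any(p$start[-1] != p$end[-nrow(p)])))
      msgs <- c(msgs, "provenance intervals must partition the gapped length")
  }
  if (length(msgs)) msgs else TRUE
})

#' AlignmentStats: summary statistics of a composite alignment
#'
#' Per-chromosome (or aggregated) alignment summary in the style of a
#' whole-genome alignment report: lengths, coverage, identity, gap-size
#' spectrum on each side, and N-exchange tallies.  All counts are in bp.
#'
#' @slot stats named numeric vector; see \code{\link{computeStats}}.
#' @exportClass AlignmentStats
setClass("AlignmentStats", representation(stats = "numeric"))

#' MSAGallery: a packed gallery of multiple sequence alignment blocks
#'
#' @slot blocks data.frame(name, width, height, x, y) with pixel origins.
#' @slot rows list of character vectors (aligned rows) per block.
#' @slot width,height canvas size in pixels.
#' @slot margin inter-block margin in pixels.
#' @slot labelHeight pixels reserved above each block for its file name.
#' @exportClass MSAGallery
setClass("MSAGallery", representation(
  blocks = "data.frame", rows = "list",
  width = "numeric", height = "numeric",
  margin = "numeric", labelHeight = "numeric"
))
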