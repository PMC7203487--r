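#' Select the master chain and order the rest
#'
#' The master chain establishes the shared coordinate frame between the
#' reference and the query genome; it is the highest-scoring chain whose
#' target is the requested reference contig (liftOver files are
#' score-sorted, so first == largest).  Remaining chains for that contig
#' are returned sorted onto the reference positive strand (ascending
#' tStart).
#'
#' @param chains list of \linkS4class{Chain} (see
#'   \code{\link{readChainFile}}).
#' @param refName reference contig name.
#' @return \code{list(master = Chain or NULL, others = list of Chain)};
#'   with a warning and NULL master when no chain targets \code{refName}.
#' @export
sortAndSelectChains <- function(chains, refName) {
  mine <- Filter(function(ch) ch@tName == refName, chains)
  if (!length(mine)) {
    warnf("no chain targets reference '%s'; empty alignment", refName)
    return(list(master = NULL, others = list()))
  }
  scores <- vapply(mine, function(ch) ch@score, numeric(1))
  master <- mine[[which.max(scores)]]
  others <- mine[-which.max(scores)]
  if (length(others)) {
    ts <- vapply(others, function(ch) ch@tStart, numeric(1))
    others <- others[order(ts)]
  }
  list(master = master, others = others)
}

## query block bases in chain-path order; qStart/qEnd in chain coords
## (i.e. on the reverse-complemented query when strand is '-')
queryChars <- function(qseq, qrc, qStart, qEnd, strand) {
  s <- if (strand == "+") qseq else qrc
  chars(substr(s, qStart + 1, qEnd))
}

## subtract a set of intervals (data.frame start,end) from [a, b);
## all 0-based half-open; returns data.frame(start, end) of the remainder
subtractIntervals <- function(a, b, claimed) {
  if (b <= a) return(data.frame(start = numeric(), end = numeric()))
  if (!nrow(claimed)) return(data.frame(start = a, end = b))
  cl <- claimed[claimed$end > a & claimed$start < b, , drop = FALSE]
  if (!nrow(cl)) return(data.frame(start = a, end = b))
  cl <- cl[order(cl$start), , drop = FALSE]
  out <- list(); cur <- a
  for (j in seq_len(nrow(cl))) {
    s <- max(a, cl$start[j]); e <- min(b, cl$end[j])
    if (s > cur) out[[length(out) + 1]] <- c(cur, s)
    cur <- max(cur, e)
  }
  if (cur < b) out[[length(out) + 1]] <- c(cur, b)
  if (!length(out)) return(data.frame(start = numeric(), end = numeric()))
  m <- do.call(rbind, out)
  data.frame(start = m[, 1], end = m[, 2])
}

#' Composite a chained alignment onto one reference contig
#'
#' Linearizes all chains targeting one reference contig into a gapped
#' reference/query pseudosequence pair with per-base provenance.  The
#' reference keeps its order and copy number (stripping '-' from the
#' gapped reference reproduces it exactly); the query is rearranged to
#' match.  The walk:
#' \enumerate{
#'   \item Master-chain aligned blocks copy both sides (class
#'     \code{syntenic}).
#'   \item dt gaps leave reference-only sequence over query '-' (class
#'     \code{unaligned_ref}) unless a secondary chain claims them.
#'   \item Secondary chains fill still-unaligned reference positions with
#'     their query sequence (class \code{intra} when the query contig
#'     matches the master's, \code{inter} otherwise); overlaps with
#'     already-aligned positions are truncated and noted.  '-' strand
#'     chains contribute reverse-complemented query sequence.
#'   \item Master-chain dq gaps pull in unaligned query sequence ('-' in
#'     the reference, class \code{unaligned_query}), minus any query
#'     intervals already claimed by a secondary chain's aligned blocks,
#'     so an inverted segment is painted once, not twice.
#' }
#'
#' @param ref reference sequences (\code{BStringSet} or named character);
#'   must contain \code{refName}.
#' @param queryGenome query sequences (\code{BStringSet} or named
#'   character).
#' @param chains list of \linkS4class{Chain}.
#' @param refName reference contig to composite; defaults to the first.
#' @return A \linkS4class{CompositeAlignment}.
#' @export
compositeAlignment <- function(ref, queryGenome, chains,
                               refName = names(ref)[1]) {
  getSeq <- function(set, nm) {
    if (is.character(set)) {
      if (!nm %in% names(set)) stopf("sequence '%s' not found", nm)
      unname(set[nm])
    } else {
      if (!nm %in% names(set)) stopf("sequence '%s' not found", nm)
      as.character(set[[nm]])
    }
  }
  refSeq <- getSeq(ref, refName)
  refLen <- nchar(refSeq)
  rch <- chars(refSeq)

  sel <- sortAndSelectChains(chains, refName)
  emptyProv <- function(cls) data.frame(
    start = 0, end = refLen, class = cls, chainId = NA_real_,
    qName = NA_character_, qStrand = NA_character_,
    stringsAsFactors = FALSE)
  if (is.null(sel$master))
    return(new("CompositeAlignment", refGapped = refSeq,
               queryGapped = strrep("-", refLen),
               provenance = emptyProv("unaligned_ref"), refName = refName))

  master <- sel$master
  qCache <- new.env(parent = emptyenv())
  getQ <- function(nm) {
    if (!exists(nm, qCache)) {
      s <- getSeq(queryGenome, nm)
      assign(nm, list(seq = s, rc = revcompChr(s), len = nchar(s)), qCache)
    }
    get(nm, qCache)
  }

  qb <- rep("-", refLen)                     # query base per ref position
  cls <- rep("unaligned_ref", refLen)
  cid <- rep(NA_real_, refLen)
  qnm <- rep(NA_character_, refLen)
  qstr <- rep(NA_character_, refLen)

  paintBlocks <- function(ch, class) {
    q <- getQ(ch@qName)
    bl <- chainBlockIntervals(ch)
    truncated <- 0
    for (j in seq_len(nrow(bl))) {
      pos <- seq.int(bl$tStart[j] + 1, bl$tEnd[j])      # 1-based ref
      if (any(pos > refLen))
        stopf("chain %d exceeds reference length %d", ch@chainId, refLen)
      bases <- queryChars(q$seq, q$rc, bl$qStart[j], bl$qEnd[j], ch@qStrand)
      free <- qb[pos] == "-"
      truncated <- truncated + sum(!free)
      sel <- pos[free]
      qb[sel] <<- bases[free]
      cls[sel] <<- class
      cid[sel] <<- ch@chainId
      qnm[sel] <<- ch@qName
      qstr[sel] <<- ch@qStrand
    }
    truncated
  }

  paintBlocks(master, "syntenic")
  claimed <- list()                          # query plus-strand intervals
  for (ch in sel$others) {
    class <- if (ch@qName == master@qName) "intra" else "inter"
    tr <- paintBlocks(ch, class)
    if (tr > 0)
      message(sprintf(
        "chain %d: %d bp overlapped already-aligned reference; truncated",
        ch@chainId, tr))
    bl <- chainBlockIntervals(ch)
    qlen <- getQ(ch@qName)$len
    plus <- if (ch@qStrand == "+")
      data.frame(start = bl$qStart, end = bl$qEnd)
    else data.frame(start = qlen - bl$qEnd, end = qlen - bl$qStart)
    plus$qName <- ch@qName
    claimed[[length(claimed) + 1]] <- plus
  }
  claimed <- if (length(claimed)) do.call(rbind, claimed)
             else data.frame(start = numeric(), end = numeric(),
                             qName = character())

  ## master dq gaps -> insertions of unique query sequence
  mq <- getQ(master@qName)
  bl <- chainBlockIntervals(master)
  b <- master@blocks
  insPos <- numeric(); insSeq <- character()
  for (j in seq_len(nrow(b))) {
    if (b$dq[j] <= 0) next
    a <- bl$qEnd[j]; z <- bl$qEnd[j] + b$dq[j]          # chain coords
    plusIv <- if (master@qStrand == "+") c(a, z)
              else c(mq$len - z, mq$len - a)
    cl <- claimed[claimed$qName == master@qName, c("start", "end"),
                  drop = FALSE]
    keep <- subtractIntervals(plusIv[1], plusIv[2], cl)
    if (!nrow(keep)) next
    if (master@qStrand == "-") {             # back to chain coords
      keep <- data.frame(start = mq$len - keep$end, end = mq$len - keep$start)
      keep <- keep[order(keep$start), , drop = FALSE]
    }
    pieces <- vapply(seq_len(nrow(keep)), function(r) paste(
      queryChars(mq$seq, mq$rc, keep$start[r], keep$end[r], master@qStrand),
      collapse = ""), character(1))
    insPos <- c(insPos, bl$tEnd[j] + b$dt[j])           # before next block
    insSeq <- c(insSeq, paste(pieces, collapse = ""))
  }

  ## linearize: walk reference, splicing insertions in
  ord <- order(insPos)
  insPos <- insPos[ord]; insSeq <- insSeq[ord]
  refPieces <- character(); qPieces <- character()
  provPieces <- list()
  cur <- 0                                    # 0-based ref position
  cuts <- c(insPos, refLen)
  for (j in seq_along(cuts)) {
    if (cuts[j] > cur) {
      span <- seq.int(cur + 1, cuts[j])
      refPieces <- c(refPieces, paste(rch[span], collapse = ""))
      qPieces <- c(qPieces, paste(qb[span], collapse = ""))
      provPieces[[length(provPieces) + 1]] <- data.frame(
        class = cls[span], chainId = cid[span], qName = qnm[span],
        qStrand = qstr[span], stringsAsFactors = FALSE)
      cur <- cuts[j]
    }
    if (j <= length(insPos)) {
      L <- nchar(insSeq[j])
      refPieces <- c(refPieces, strrep("-", L))
      qPieces <- c(qPieces, insSeq[j])
      provPieces[[length(provPieces) + 1]] <- data.frame(
        class = rep("unaligned_query", L), chainId = rep(master@chainId, L),
        qName = rep(master@qName, L), qStrand = rep(master@qStrand, L),
        stringsAsFactors = FALSE)
    }
  }
  pv <- do.call(rbind, provPieces)
  key <- paste(pv$class, pv$chainId, pv$qName, pv$qStrand, sep = "\r")
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  first <- ends - r$lengths + 1
  prov <- data.frame(
    start = starts, end = ends,
    class = pv$class[first], chainId = pv$chainId[first],
    qName = pv$qName[first], qStrand = pv$qStrand[first],
    stringsAsFactors = FALSE)

  new("CompositeAlignment",
      refGapped = paste(refPieces, collapse = ""),
      queryGapped = paste(qPieces, collapse = ""),
      provenance = prov, refName = refName)
}

setMethod("show", "CompositeAlignment", function(object) {
  cat(sprintf("CompositeAlignment of '%s': gapped length %d, %d provenance intervals\n",
              object@refName, nchar(object@refGapped),
              nrow(object@provenance)))
  tab <- tapply(object@provenance$end - object@provenance$start,
                object@provenance$class, sum)
  for (nm in names(tab)) cat(sprintf("  %-15s %d bp\n", nm, tab[[nm]]))
})

#' @describeIn compositeAlignment provenance interval accessor.
#' @param comp a \linkS4class{CompositeAlignment}.
#' @export
provenance <- function(comp) comp@provenance

#' @describeIn compositeAlignment gapped sequence accessors.
#' @export
refGapped <- function(comp) comp@refGapped

#' @rdname compositeAlignment
#' @export
queryGapped <- function(comp) comp@queryGapped

#' Difference columns of a composite alignment
#'
#' The two center columns of the four-column alignment view: per gapped
#' position, equal bases (case-insensitive) give background '-' on both
#' sides; a mismatch puts the reference base in \code{refUnique} and the
#' query base in \code{queryUnique}; a gap on one side puts the other
#' side's base in its unique column only.
#'
#' @param comp a \linkS4class{CompositeAlignment}.
#' @return \code{list(refUnique, queryUnique)} of gapped-length strings.
#' @export
differenceColumns <- function(comp) {
  r <- chars(comp@refGapped); q <- chars(comp@queryGapped)
  same <- toupper(r) == toupper(q)
  ru <- ifelse(same | r == "-", "-", r)
  qu <- ifelse(same | q == "-", "-", q)
  list(refUnique = paste(ru, collapse = ""),
       queryUnique = paste(qu, collapse = ""))
}

#' Reference sequence not covered by the alignment
#'
#' Concatenates the reference bases at gapped positions where the query
#' side is '-' (unaligned reference), i.e. subtracts the query genome
#' from the reference, one output contig per reference chromosome.
#'
#' @param comp a \linkS4class{CompositeAlignment}.
#' @return A \code{BStringSet} of length 1 named after the reference
#'   contig (width 0 when the alignment covers everything).
#' @export
uniqueSequence <- function(comp) {
  r <- chars(comp@refGapped); q <- chars(comp@queryGapped)
  s <- paste(r[q == "-"], collapse = "")
  out <- Biostrings::BStringSet(s)
  names(out) <- comp@refName
  out
}

#' Alignment summary statistics
#'
#' Computes per-chromosome alignment statistics from a composite:
#' \describe{
#'   \item{refLenWithN / refLenNoN}{ungapped reference length, with and
#'     without N bases.}
#'   \item{alignmentLength}{positions where both sides carry a base and
#'     neither is N.}
#'   \item{unalignedRef}{reference positions with no aligned query.}
#'   \item{identical / nonIdentical}{case-insensitive base agreement
#'     within the alignment (N positions excluded from both tallies and
#'     reported as the N-exchange fields instead); their sum equals
#'     \code{alignmentLength}.}
#'   \item{coveragePct}{100 * alignmentLength / refLenNoN.}
#'   \item{identityPct}{100 * identical / alignmentLength.}
#'   \item{refGapCount, refGapsGt10/100/1000}{maximal runs of unaligned
#'     reference sequence (query-side '-'), total and exceeding each
#'     length threshold.}
#'   \item{queryGapCount, queryGapsGt10/100/1000}{maximal runs of '-'
#'     introduced into the reference (query insertions).}
#'   \item{refNToQueryBp / queryNToRefBp}{aligned positions where the
#'     reference (resp. query) base is N.}
#' }
#'
#' @param comp a \linkS4class{CompositeAlignment}, or a list of them to
#'   aggregate genome-wide (gap runs are then counted per chromosome and
#'   summed).
#' @return An \linkS4class{AlignmentStats}.
#' @export
computeStats <- function(comp) {
  if (is.list(comp)) {
    parts <- lapply(comp, function(cc) computeStats(cc)@stats)
    total <- Reduce(`+`, parts)
    total["coveragePct"] <- if (total["refLenNoN"] > 0)
      100 * total["alignmentLength"] / total["refLenNoN"] else 0
    total["identityPct"] <- if (total["alignmentLength"] > 0)
      100 * total["identical"] / total["alignmentLength"] else 0
    return(new("AlignmentStats", stats = total))
  }
  r <- chars(comp@refGapped); q <- chars(comp@queryGapped)
  rUp <- toupper(r); qUp <- toupper(q)
  rBase <- r != "-"; qBase <- q != "-"
  aligned <- rBase & qBase
  refN <- aligned & rUp == "N"
  qryN <- aligned & qUp == "N" & rUp != "N"
  alen <- sum(aligned) - sum(refN) - sum(qryN)
  ident <- sum(aligned & !refN & !qryN & rUp == qUp)
  refGapRuns <- trueRuns(!qBase)             # unaligned reference runs
  qryGapRuns <- trueRuns(!rBase)             # gaps punched into reference
  gapStats <- function(runs, side) {
    v <- c(nrow(runs), sum(runs$length > 10), sum(runs$length > 100),
           sum(runs$length > 1000))
    names(v) <- paste0(side, c("GapCount", "GapsGt10", "GapsGt100",
                               "GapsGt1000"))
    v
  }
  refLenWithN <- sum(rBase)
  refLenNoN <- sum(rBase & rUp != "N")
  if (alen == 0) warnf("empty alignment for '%s'; percentages are 0",
                       comp@refName)
  s <- c(
    refLenWithN = refLenWithN, refLenNoN = refLenNoN,
    alignmentLength = alen, unalignedRef = sum(rBase & !qBase),
    coveragePct = if (refLenNoN > 0) 100 * alen / refLenNoN else 0,
    identical = ident, nonIdentical = alen - ident,
    identityPct = if (alen > 0) 100 * ident / alen else 0,
    gapStats(refGapRuns, "ref"), gapStats(qryGapRuns, "query"),
    refNToQueryBp = sum(refN), queryNToRefBp = sum(qryN))
  new("AlignmentStats", stats = s)
}

#' @describeIn computeStats named numeric vector of the statistics.
#' @param x an \code{AlignmentStats}.
#' @export
alignmentStats <- function(x) x@stats

setMethod("show", "AlignmentStats", function(object) {
  s <- object@stats
  for (nm in names(s))
    cat(sprintf("  %-18s %s\n", nm,
                if (grepl("Pct$", nm)) sprintf("%.2f%%", s[[nm]])
                else format(s[[nm]], big.mark = ",")))
})

#' Write an alignment statistics table
#'
#' One row per statistic, one column per chromosome plus a genome-wide
#' aggregate, as tab-separated text.
#'
#' @param statsList named list of \linkS4class{AlignmentStats} (one per
#'   reference chromosome).
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeStatsTable <- function(statsList, path) {
  cols <- lapply(statsList, alignmentStats)
  df <- data.frame(feature = names(cols[[1]]))
  for (nm in names(cols)) df[[nm]] <- unname(cols[[nm]])
  if (length(cols) > 1) {
    agg <- Reduce(`+`, cols)
    agg["coveragePct"] <- if (agg["refLenNoN"] > 0)
      100 * agg["alignmentLength"] / agg["refLenNoN"] else 0
    agg["identityPct"] <- if (agg["alignmentLength"] > 0)
      100 * agg["identical"] / agg["alignmentLength"] else 0
    df[["genome"]] <- unname(agg)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-chain coverage profile of the reference
#'
#' Coverage of each reference contig by the union of aligned blocks of
#' its top-k chains (by score), for k = 1, 2, 3 and all, with and without
#' N positions, plus the split between chains from the homologous query
#' chromosome and all other chromosomes.  Homology is a configurable name
#' map from query contig name to reference contig name (e.g.
#' \code{c(chr2A = "chr2", chr2B = "chr2")}); by default a query contig
#' is homologous when its name equals the reference contig's.
#'
#' @param chains list of \linkS4class{Chain}.
#' @param refGenome reference sequences (for lengths and N positions).
#' @param homologMap named character vector qName -> refName, or NULL.
#' @param ks values of k (use \code{Inf} for all chains).
#' @return \code{list(perK = data.frame, homolog = data.frame)}.
#' @export
chainCoverageProfile <- function(chains, refGenome, homologMap = NULL,
                                 ks = c(1, 2, 3, Inf)) {
  nms <- names(refGenome)
  getSeq <- function(nm) if (is.character(refGenome)) refGenome[[nm]]
                         else as.character(refGenome[[nm]])
  unionCover <- function(chs, nonN) {
    if (!length(chs)) return(c(0, 0))
    ivs <- do.call(rbind, lapply(chs, function(ch) {
      bl <- chainBlockIntervals(ch); cbind(bl$tStart, bl$tEnd)
    }))
    ir <- IRanges::reduce(IRanges::IRanges(start = ivs[, 1] + 1,
                                           end = ivs[, 2]))
    cov <- sum(IRanges::width(ir))
    covNoN <- sum(vapply(seq_along(ir), function(j)
      sum(nonN[IRanges::start(ir)[j]:IRanges::end(ir)[j]]), numeric(1)))
    c(cov, covNoN)
  }
  perK <- list(); hom <- list()
  for (nm in nms) {
    s <- getSeq(nm)
    nonN <- toupper(chars(s)) != "N"
    lenAll <- nchar(s); lenNoN <- sum(nonN)
    mine <- Filter(function(ch) ch@tName == nm, chains)
    if (length(mine)) {
      sc <- vapply(mine, function(ch) ch@score, numeric(1))
      mine <- mine[order(sc, decreasing = TRUE)]
    }
    for (k in ks) {
      top <- if (is.finite(k)) utils::head(mine, k) else mine
      cv <- unionCover(top, nonN)
      perK[[length(perK) + 1]] <- data.frame(
        refName = nm, k = k, coveredBp = cv[1],
        coveredFrac = if (lenAll) cv[1] / lenAll else 0,
        coveredBpNoN = cv[2],
        coveredFracNoN = if (lenNoN) cv[2] / lenNoN else 0)
    }
    isHom <- vapply(mine, function(ch) {
      mapped <- if (!is.null(homologMap) && ch@qName %in% names(homologMap))
        homologMap[[ch@qName]] else ch@qName
      identical(mapped, nm)
    }, logical(1))
    cvH <- unionCover(mine[isHom], nonN)
    cvA <- unionCover(mine, nonN)
    hom[[length(hom) + 1]] <- data.frame(
      refName = nm, homologBp = cvH[1], homologBpNoN = cvH[2],
      nonHomologBp = cvA[1] - cvH[1], nonHomologBpNoN = cvA[2] - cvH[2],
      homologFrac = if (lenAll) cvH[1] / lenAll else 0,
      totalFrac = if (lenAll) cvA[1] / lenAll else 0)
  }
  list(perK = do.call(rbind, perK), homolog = do.call(rbind, hom))
}

#' Background colors of the provenance classes
#'
#' White for syntenic (master chain) and unaligned sequence, blue for
#' intrachromosomal secondary chains, red for interchromosomal ones.
#'
#' @return named list of RGB triples (0-255).
#' @export
provenanceColors <- function() list(
  syntenic = c(255, 255, 255),
  intra = c(180, 200, 255),
  inter = c(255, 180, 180),
  unaligned_ref = c(255, 255, 255),
  unaligned_query = c(255, 255, 255))

#' Render the four-column alignment view
#'
#' Columns left to right: gapped reference, reference-unique variants,
#' query-unique variants, gapped query.  The two middle (difference)
#' columns carry a background tint per provenance class (white syntenic,
#' blue intrachromosomal, red interchromosomal) so inversions,
#' transpositions and translocations are visible at any zoom.
#'
#' @param comp a \linkS4class{CompositeAlignment}.
#' @param palette see \code{\link{defaultPalette}}.
#' @param rowWidth bases per row (default 100).
#' @param colGap pixels between columns.
#' @return numeric raster array \code{[height, width, 3]}.
#' @export
renderAlignmentColumns <- function(comp, palette = defaultPalette(),
                                   rowWidth = 100, colGap = 3) {
  G <- nchar(comp@refGapped)
  nRows <- ceiling(G / rowWidth)
  d <- differenceColumns(comp)
  seqs <- c(comp@refGapped, d$refUnique, d$queryUnique, comp@queryGapped)
  ## per-position provenance class expanded once
  pv <- comp@provenance
  cls <- rep(pv$class, pv$end - pv$start)
  bgPal <- provenanceColors()
  bg <- vapply(bgPal[cls], identity, numeric(3)) / 255
  w <- 4 * rowWidth + 3 * colGap
  img <- blankCanvas(nRows, w, palette)
  pos <- seq_len(G) - 1
  px <- pos %% rowWidth
  py <- pos %/% rowWidth
  for (colIdx in 1:4) {
    ch <- chars(seqs[colIdx])
    x <- px + (colIdx - 1) * (rowWidth + colGap)
    colr <- paletteLookup(palette, ch)
    if (colIdx %in% c(2, 3)) {               # difference columns: tint
      isGap <- ch == "-"
      colr[, isGap] <- bg[, isGap]
    }
    img <- paintPixels(img, x, py, colr)
  }
  img
}
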