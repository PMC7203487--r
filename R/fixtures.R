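#' Generate a synthetic genome
#'
#' Deterministic (seeded) random genome emulating features that are
#' visible in nucleotide rasters: regional G/C content shifts (isochores
#' appear as background color changes) and planted tandem repeat arrays
#' (which appear as a texture).
#'
#' @param nContigs number of contigs.
#' @param lengths integer vector of contig lengths (recycled).
#' @param gcRegions optional data.frame(contig, start, end, gc) of 1-based
#'   inclusive regions with a target GC fraction; elsewhere GC = 0.41
#'   (typical vertebrate average).
#' @param tandemRepeats optional data.frame(contig, start, unit, copies):
#'   plant \code{strrep(unit, copies)} at \code{start} (1-based),
#'   overwriting the random sequence.
#' @param seed integer seed controlling all randomness.
#' @param path optional FASTA output path; when given the file is written
#'   and the path returned invisibly alongside the sequences.
#' @return A \code{BStringSet} named \code{chr1..chrN} (and the written
#'   file when \code{path} is given).
#' @export
genGenome <- function(nContigs = 3, lengths = 1000, gcRegions = NULL,
                      tandemRepeats = NULL, seed = 1, path = NULL) {
  set.seed(seed)
  lengths <- rep_len(lengths, nContigs)
  baseGC <- 0.41
  seqs <- character(nContigs)
  for (i in seq_len(nContigs)) {
    L <- lengths[i]
    gc <- rep(baseGC, L)
    nm <- paste0("chr", i)
    if (!is.null(gcRegions)) {
      rg <- gcRegions[gcRegions$contig == nm, , drop = FALSE]
      for (j in seq_len(nrow(rg)))
        gc[rg$start[j]:min(rg$end[j], L)] <- rg$gc[j]
    }
    isGC <- stats::runif(L) < gc
    half <- stats::runif(L) < 0.5
    b <- ifelse(isGC, ifelse(half, "G", "C"), ifelse(half, "A", "T"))
    if (!is.null(tandemRepeats)) {
      tr <- tandemRepeats[tandemRepeats$contig == nm, , drop = FALSE]
      for (j in seq_len(nrow(tr))) {
        arr <- chars(strrep(tr$unit[j], tr$copies[j]))
        pos <- tr$start[j] + seq_along(arr) - 1
        b[pos[pos <= L]] <- arr[pos <= L]
      }
    }
    seqs[i] <- paste(b, collapse = "")
  }
  names(seqs) <- paste0("chr", seq_len(nContigs))
  x <- Biostrings::BStringSet(seqs)
  S4Vectors::mcols(x) <- S4Vectors::DataFrame(description = names(seqs))
  if (!is.null(path)) writeFastaFile(x, path)
  x
}

#' Generate nested gene annotations for a genome
#'
#' Places \code{nGenes} non-overlapping gene models per genome (spread
#' over its contigs), each a GFF3-valid nest gene > mRNA > exons > CDS
#' within contig bounds, with 1-3 exons per gene and CDS inside exons.
#'
#' @param genome a \code{BStringSet} (or named character).
#' @param nGenes total number of genes.
#' @param seed integer seed.
#' @param path optional GFF3 output path.
#' @return data.frame of GFF columns (and the written file when
#'   \code{path} is given).
#' @export
genFeatures <- function(genome, nGenes = 5, seed = 1, path = NULL) {
  set.seed(seed)
  nms <- names(genome)
  lens <- if (is.character(genome)) nchar(genome)
          else Biostrings::width(genome)
  rows <- list()
  addRow <- function(seqid, type, start, end, strand, attrs)
    rows[[length(rows) + 1]] <<- data.frame(
      seqid = seqid, source = "seqcanvas", type = type, start = start,
      end = end, score = ".", strand = strand, phase = ".",
      attributes = attrs, stringsAsFactors = FALSE)
  contigOf <- sample(seq_along(nms), nGenes, replace = TRUE,
                     prob = lens / sum(lens))
  nextFree <- stats::setNames(rep(1, length(nms)), nms)
  for (g in seq_len(nGenes)) {
    ci <- contigOf[g]; nm <- nms[ci]; L <- lens[ci]
    glen <- sample(60:200, 1)
    lo <- nextFree[nm]
    if (lo + glen > L) next                  # contig full; skip
    gs <- lo + sample(0:min(50, L - lo - glen), 1)
    ge <- gs + glen - 1
    nextFree[nm] <- ge + 10
    strand <- sample(c("+", "-"), 1)
    gid <- sprintf("gene%03d", g)
    addRow(nm, "gene", gs, ge, strand,
           sprintf("ID=%s;Name=GENE%03d", gid, g))
    addRow(nm, "mRNA", gs, ge, strand,
           sprintf("ID=%s.t1;Parent=%s", gid, gid))
    nEx <- sample(1:3, 1)
    bounds <- sort(sample(seq.int(gs, ge), 2 * nEx))
    for (e in seq_len(nEx)) {
      es <- bounds[2 * e - 1]; ee <- bounds[2 * e]
      addRow(nm, "exon", es, ee, strand,
             sprintf("ID=%s.e%d;Parent=%s.t1", gid, e, gid))
      if (ee - es >= 2)
        addRow(nm, "CDS", es + 1, ee - 1, strand,
               sprintf("ID=%s.c%d;Parent=%s.t1", gid, e, gid))
    }
  }
  df <- do.call(rbind, rows)
  if (!is.null(path)) {
    con <- file(path, "w")
    writeLines("##gff-version 3", con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    close(con)
  }
  df
}

#' Build a mutation recipe
#'
#' A recipe lists the exact edits applied to a reference to produce a
#' query genome, chosen (seeded) so that no two events overlap or touch:
#' SNPs, one-sided indels (\code{side = "ref"}: sequence present only in
#' the reference, a dt gap; \code{side = "query"}: query insertion, a dq
#' gap), inversions (emitted as '-' strand secondary chains) and
#' translocations (segments moved to a second query contig, emitted as
#' separate '+' chains).  Because the recipe is the ground truth, the
#' alignment statistics it implies are known by construction.
#'
#' @param refLen reference contig length.
#' @param nSnp number of substitutions.
#' @param indels list of \code{c(side=, length=)} or data.frame
#'   (side, length).
#' @param inversions integer vector of inversion lengths.
#' @param translocations integer vector of translocated segment lengths.
#' @param seed integer seed.
#' @return list describing the recipe (positions are 0-based).
#' @export
mutationRecipe <- function(refLen = 3000, nSnp = 5,
                           indels = data.frame(side = character(),
                                               length = integer()),
                           inversions = integer(),
                           translocations = integer(), seed = 1) {
  set.seed(seed)
  if (is.list(indels) && !is.data.frame(indels))
    indels <- do.call(rbind.data.frame, indels)
  spans <- data.frame(type = character(), len = numeric(), side = character())
  add <- function(type, len, side = "") spans <<- rbind(
    spans, data.frame(type = type, len = len, side = side))
  for (i in seq_len(nSnp)) add("snp", 1)
  for (i in seq_len(nrow(indels))) {
    side <- as.character(indels$side[i]); len <- indels$length[i]
    # a query insertion occupies 0 reference bases (an insertion point)
    add(if (side == "ref") "del" else "ins", len, side)
  }
  for (L in inversions) add("inv", L)
  for (L in translocations) add("trans", L)
  nEv <- nrow(spans)
  if (!nEv) return(list(refLen = refLen, events = spans[0, ], seed = seed))
  refSpan <- ifelse(spans$type == "ins", 0, spans$len)
  gap <- 5                                   # min separation between events
  need <- sum(refSpan) + (nEv + 2) * gap     # keeps both chain ends aligned
  if (need > refLen)
    stopf("recipe needs %d bp but reference is %d bp", need, refLen)
  o <- sample.int(nEv)                       # random order along the ref
  slack <- refLen - need
  cutsAt <- sort(sample.int(slack + 1, nEv, replace = TRUE) - 1)
  pos <- numeric(nEv)
  cur <- gap
  for (j in seq_len(nEv)) {
    pos[j] <- cur + cutsAt[j]
    cur <- cur + refSpan[o[j]] + gap
  }
  ev <- spans[o, , drop = FALSE]
  ev$pos <- pos                              # 0-based ref position
  ev <- ev[order(ev$pos), , drop = FALSE]
  rownames(ev) <- NULL
  list(refLen = refLen, events = ev, seed = seed)
}

#' Apply a mutation recipe: query genome + chain file + ground truth
#'
#' Applies the recipe's edits to the reference to produce the query
#' genome (contig \code{q1}, plus \code{q2} holding translocated
#' segments), emits the exactly corresponding chain set (one master '+'
#' chain, a '-' strand chain per inversion, a separate \code{q2} chain
#' per translocation) and the alignment statistics the recipe implies,
#' computed during construction and independently of
#' \code{\link{computeStats}}.
#'
#' @param ref reference sequences (first contig is mutated).
#' @param recipe a \code{\link{mutationRecipe}}.
#' @param queryFasta,chainPath optional output paths.
#' @return list(query = BStringSet, chains = list of Chain,
#'   groundTruth = named numeric vector matching
#'   \code{\link{alignmentStats}} names).
#' @export
mutateAndChain <- function(ref, recipe, queryFasta = NULL,
                           chainPath = NULL) {
  set.seed(recipe$seed + 1)
  refName <- names(ref)[1]
  refSeq <- if (is.character(ref)) ref[[refName]]
            else as.character(ref[[refName]])
  refLen <- nchar(refSeq)
  if (recipe$refLen != refLen)
    stopf("recipe is for a %d bp reference, got %d bp", recipe$refLen,
          refLen)
  ev <- recipe$events
  rch <- chars(refSeq)
  alphabet <- c("A", "C", "G", "T")

  ## --- build q1 (descending ref position keeps coordinates stable) ---
  q1 <- rch
  q2parts <- character()
  if (nrow(ev)) for (j in rev(seq_len(nrow(ev)))) {
    p <- ev$pos[j]; L <- ev$len[j]
    switch(ev$type[j],
      snp = {
        old <- toupper(q1[p + 1])
        q1[p + 1] <- sample(setdiff(alphabet, old), 1)
      },
      del = q1 <- q1[-seq.int(p + 1, p + L)],
      ins = {
        insBases <- sample(alphabet, L, replace = TRUE)
        q1 <- append(q1, insBases, after = p)
      },
      inv = {
        seg <- q1[seq.int(p + 1, p + L)]
        q1[seq.int(p + 1, p + L)] <- chars(revcompChr(paste(seg,
                                                            collapse = "")))
      },
      trans = {
        q2parts <- c(q2parts,
                     paste(q1[seq.int(p + 1, p + L)], collapse = ""))
        q1 <- q1[-seq.int(p + 1, p + L)]
      })
  }
  ## q2parts collected in descending ref order; restore ascending
  q2parts <- rev(q2parts)
  q1seq <- paste(q1, collapse = "")
  q2seq <- paste(q2parts, collapse = "")
  q1len <- nchar(q1seq); q2len <- nchar(q2seq)

  num <- as.numeric                          # chain slots are doubles
  ## --- master chain blocks + per-event query coordinates ---
  blocks <- list(); insAt <- 0               # query offset shift so far
  prevRef <- 0; qOff <- 0
  pend <- function(size, dt, dq) blocks[[length(blocks) + 1]] <<-
    c(size = size, dt = dt, dq = dq)
  secondary <- list()
  q2cursor <- 0
  chainId <- 1
  masterScore <- 100 * refLen
  if (nrow(ev)) for (j in seq_len(nrow(ev))) {
    p <- ev$pos[j]; L <- ev$len[j]; type <- ev$type[j]
    if (type == "snp") next
    size <- p - prevRef                      # aligned run before the event
    qPosAtP <- p + qOff                      # q1 coord aligned with ref p
    switch(type,
      del = { pend(size, L, 0); qOff <- qOff - L; prevRef <- p + L },
      ins = { pend(size, 0, L); qOff <- qOff + L; prevRef <- p },
      inv = {
        pend(size, L, L)
        ## '-' strand chain over the inverted q1 segment
        chainId <- chainId + 1
        secondary[[length(secondary) + 1]] <- new("Chain",
          score = num(L), tName = refName, tSize = num(refLen),
          tStrand = "+", tStart = num(p), tEnd = num(p + L), qName = "q1",
          qSize = num(q1len), qStrand = "-",
          qStart = num(q1len - (qPosAtP + L)), qEnd = num(q1len - qPosAtP),
          chainId = num(chainId),
          blocks = data.frame(size = num(L), dt = 0, dq = 0))
        prevRef <- p + L
      },
      trans = {
        pend(size, L, 0); qOff <- qOff - L
        chainId <- chainId + 1
        secondary[[length(secondary) + 1]] <- new("Chain",
          score = num(L), tName = refName, tSize = num(refLen),
          tStrand = "+", tStart = num(p), tEnd = num(p + L), qName = "q2",
          qSize = num(q2len), qStrand = "+", qStart = num(q2cursor),
          qEnd = num(q2cursor + L), chainId = num(chainId),
          blocks = data.frame(size = num(L), dt = 0, dq = 0))
        q2cursor <- q2cursor + L
        prevRef <- p + L
      })
  }
  pend(refLen - prevRef, 0, 0)
  b <- as.data.frame(do.call(rbind, blocks))
  b <- b[b$size > 0 | b$dt > 0 | b$dq > 0, , drop = FALSE]
  ## merge zero-size rows into predecessors (cannot occur with gapped
  ## recipes, but keep the chain well-formed)
  stopifnot(all(b$size >= 1))
  b[] <- lapply(b, as.numeric)
  master <- new("Chain", score = num(masterScore), tName = refName,
                tSize = num(refLen), tStrand = "+", tStart = 0,
                tEnd = num(refLen), qName = "q1", qSize = num(q1len),
                qStrand = "+", qStart = 0, qEnd = num(q1len), chainId = 1,
                blocks = b)
  validObject(master)
  chains <- c(list(master), secondary)

  ## --- ground truth, from the recipe alone ---
  nSnp <- sum(ev$type == "snp")
  delLens <- ev$len[ev$type == "del"]
  insLens <- ev$len[ev$type == "ins"]
  alen <- refLen - sum(delLens)              # dels unaligned; inv/trans align
  gt <- c(
    refLenWithN = refLen, refLenNoN = refLen,
    alignmentLength = alen, unalignedRef = sum(delLens),
    coveragePct = 100 * alen / refLen,
    identical = alen - nSnp, nonIdentical = nSnp,
    identityPct = if (alen > 0) 100 * (alen - nSnp) / alen else 0,
    refGapCount = length(delLens), refGapsGt10 = sum(delLens > 10),
    refGapsGt100 = sum(delLens > 100), refGapsGt1000 = sum(delLens > 1000),
    queryGapCount = length(insLens), queryGapsGt10 = sum(insLens > 10),
    queryGapsGt100 = sum(insLens > 100),
    queryGapsGt1000 = sum(insLens > 1000),
    refNToQueryBp = 0, queryNToRefBp = 0)

  query <- Biostrings::BStringSet(c(q1 = q1seq,
                                    q2 = if (q2len) q2seq else NULL))
  if (!is.null(queryFasta)) writeFastaFile(query, queryFasta)
  if (!is.null(chainPath)) writeChainFile(chains, chainPath)
  list(query = query, chains = chains, groundTruth = gt)
}

#' Write a self-contained synthetic test dataset
#'
#' Generates a reference genome, gene annotations, a mutated query genome
#' and the corresponding chain file into one directory.
#'
#' @param dir output directory (created).
#' @param seed integer seed.
#' @return invisible list of the written paths.
#' @export
writeFixtureDataset <- function(dir, seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ref <- genGenome(nContigs = 1, lengths = 3000, seed = seed,
                   path = file.path(dir, "ref.fa"))
  genFeatures(ref, nGenes = 5, seed = seed,
              path = file.path(dir, "ref.gff3"))
  rec <- mutationRecipe(refLen = 3000, nSnp = 8,
                        indels = data.frame(side = c("ref", "query"),
                                            length = c(40, 12)),
                        inversions = 200, translocations = 150,
                        seed = seed)
  mutateAndChain(ref, rec, queryFasta = file.path(dir, "query.fa"),
                 chainPath = file.path(dir, "ref_to_query.chain"))
  invisible(list(ref = file.path(dir, "ref.fa"),
                 gff = file.path(dir, "ref.gff3"),
                 query = file.path(dir, "query.fa"),
                 chain = file.path(dir, "ref_to_query.chain")))
}
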