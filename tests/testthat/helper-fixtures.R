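# shared test helpers: in-code fixtures, no files checked in

# minimal GRanges feature set with the mcols readAnnotations produces
makeFeatures <- function(seqid, type, start, end, strand = "+",
                         label = "") {
  ft <- ifelse(type %in% c("gene", "mRNA", "exon", "CDS"), type, "other")
  ft[type == "transcript"] <- "mRNA"
  gr <- GenomicRanges::GRanges(
    seqnames = seqid, ranges = IRanges::IRanges(start = start, end = end),
    strand = strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "test",
    ftype = factor(ft, levels = c("gene", "mRNA", "exon", "CDS", "other")),
    type = type, label = rep_len(label, length(gr)))
  gr
}

# brute-force per-base priority oracle for annotation flattening
flattenOracle <- function(features, contigLengths) {
  prio <- c(gene = 1, mRNA = 2, exon = 3, CDS = 4)
  out <- lapply(contigLengths, function(L) integer(L))
  sq <- as.character(GenomicRanges::seqnames(features))
  ft <- as.character(S4Vectors::mcols(features)$ftype)
  for (j in seq_along(features)) {
    p <- prio[ft[j]]
    if (is.na(p)) next
    L <- contigLengths[[sq[j]]]
    for (b in seq(max(1, GenomicRanges::start(features)[j]),
                  min(L, GenomicRanges::end(features)[j])))
      out[[sq[j]]][b] <- max(out[[sq[j]]][b], p)
  }
  unlist(lapply(names(contigLengths), function(nm) out[[nm]]),
         use.names = FALSE)
}

# positional difference-column oracle: scalar loop, independent of the
# vectorized implementation
differenceOracle <- function(refG, qryG) {
  r <- strsplit(refG, "")[[1]]; q <- strsplit(qryG, "")[[1]]
  ru <- character(length(r)); qu <- character(length(q))
  for (i in seq_along(r)) {
    if (toupper(r[i]) == toupper(q[i])) { ru[i] <- "-"; qu[i] <- "-" }
    else if (q[i] == "-") { ru[i] <- r[i]; qu[i] <- "-" }
    else if (r[i] == "-") { ru[i] <- "-"; qu[i] <- q[i] }
    else { ru[i] <- r[i]; qu[i] <- q[i] }
  }
  list(refUnique = paste(ru, collapse = ""),
       queryUnique = paste(qu, collapse = ""))
}

# a small random recipe drawing event sizes across the gap thresholds
randomRecipe <- function(seed, refLen = 2500) {
  set.seed(seed)
  small <- refLen < 1000                     # keep events inside short refs
  sizes <- if (small) c(2, 5, 12, 30) else c(3, 8, 15, 40, 120, 400)
  nIndel <- sample(0:3, 1)
  indels <- if (nIndel > 0) data.frame(
    side = sample(c("ref", "query"), nIndel, replace = TRUE),
    length = sample(sizes, nIndel, replace = TRUE))
  else data.frame(side = character(), length = integer())
  mutationRecipe(
    refLen = refLen, nSnp = sample(0:6, 1), indels = indels,
    inversions = if (stats::runif(1) < 0.5)
      sample(if (small) 15:50 else 50:200, 1) else integer(),
    translocations = if (stats::runif(1) < 0.5)
      sample(if (small) 15:40 else 50:150, 1) else integer(),
    seed = seed)
}

tmpfile <- function(ext = "") tempfile(fileext = ext)
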