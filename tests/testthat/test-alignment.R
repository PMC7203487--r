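toyChain <- function(score = 4900, tName = "chrR", tSize = 30, t0 = 0,
                     t1 = 30, qName = "chrQ", qSize = 28, qStrand = "+",
                     q0 = 0, q1 = 28, id = 1,
                     blocks = data.frame(size = c(10, 18), dt = c(2, 0),
                                         dq = c(0, 0))) {
  new("Chain", score = score, tName = tName, tSize = tSize, tStrand = "+",
      tStart = t0, tEnd = t1, qName = qName, qSize = qSize,
      qStrand = qStrand, qStart = q0, qEnd = q1, chainId = id,
      blocks = blocks)
}

test_that("master chain is the highest score; others sort by tStart", {
  c1 <- toyChain(score = 100, id = 1, t0 = 12, t1 = 22, q0 = 0, q1 = 10,
                 blocks = data.frame(size = 10, dt = 0, dq = 0))
  c2 <- toyChain(score = 4900, id = 2)
  c3 <- toyChain(score = 50, id = 3, t0 = 2, t1 = 8, q0 = 10, q1 = 16,
                 blocks = data.frame(size = 6, dt = 0, dq = 0))
  sel <- sortAndSelectChains(list(c1, c2, c3), "chrR")
  expect_equal(sel$master@chainId, 2)
  expect_equal(vapply(sel$others, function(x) x@chainId, numeric(1)),
               c(3, 1))
  sel1 <- sortAndSelectChains(list(c2), "chrR")
  expect_length(sel1$others, 0)
  expect_warning(sortAndSelectChains(list(c1), "chrZ"), "no chain")
})

test_that("a dt gap composites as reference-only sequence", {
  set.seed(1)
  refSeq <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
  qrySeq <- paste0(substr(refSeq, 1, 10), substr(refSeq, 13, 30))
  comp <- compositeAlignment(c(chrR = refSeq), c(chrQ = qrySeq),
                             list(toyChain()))
  expect_identical(refGapped(comp), refSeq)          # no gaps in ref
  q <- queryGapped(comp)
  expect_identical(substr(q, 11, 12), "--")
  expect_identical(gsub("-", "", q), qrySeq)
  st <- alignmentStats(computeStats(comp))
  expect_equal(unname(st["alignmentLength"]), 28)
  expect_equal(unname(st["unalignedRef"]), 2)
  expect_equal(unname(st["refGapCount"]), 1)
})

test_that("a dq gap inserts query sequence and conserves the reference", {
  set.seed(2)
  refSeq <- paste(sample(c("A", "C", "G", "T"), 25, TRUE), collapse = "")
  ins <- "GGGGG"
  qrySeq <- paste0(substr(refSeq, 1, 10), ins, substr(refSeq, 11, 25))
  ch <- toyChain(tSize = 25, t1 = 25, qSize = 30, q1 = 30,
                 blocks = data.frame(size = c(10, 15), dt = c(0, 0),
                                     dq = c(5, 0)))
  comp <- compositeAlignment(c(chrR = refSeq), c(chrQ = qrySeq), list(ch))
  expect_identical(gsub("-", "", refGapped(comp)), refSeq)
  expect_identical(substr(refGapped(comp), 11, 15), "-----")
  expect_identical(substr(queryGapped(comp), 11, 15), ins)
  st <- alignmentStats(computeStats(comp))
  expect_equal(unname(st["queryGapCount"]), 1)
  expect_equal(unname(st["refGapCount"]), 0)
  pv <- provenance(comp)
  expect_true("unaligned_query" %in% pv$class)
})

test_that("secondary chains classify intra vs inter provenance", {
  set.seed(3)
  refSeq <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
  master <- toyChain(tSize = 40, t1 = 40, qName = "q1", qSize = 30,
                     q1 = 30,
                     blocks = data.frame(size = c(10, 20), dt = c(10, 0),
                                         dq = c(0, 0)))
  other <- toyChain(score = 10, id = 2, tSize = 40, t0 = 10, t1 = 20,
                    qName = "q2", qSize = 10, q0 = 0, q1 = 10,
                    blocks = data.frame(size = 10, dt = 0, dq = 0))
  q1 <- paste0(substr(refSeq, 1, 10), substr(refSeq, 21, 40))
  q2 <- substr(refSeq, 11, 20)
  comp <- compositeAlignment(c(chrR = refSeq), c(q1 = q1, q2 = q2),
                             list(master, other))
  pv <- provenance(comp)
  expect_identical(pv$class[pv$start == 10], "inter")
  st <- alignmentStats(computeStats(comp))
  expect_equal(unname(st["alignmentLength"]), 40)    # fully covered
  expect_equal(unname(st["identityPct"]), 100)
  # same-name secondary would be intra
  other2 <- toyChain(score = 10, id = 3, tSize = 40, t0 = 10, t1 = 20,
                     qName = "q1", qSize = 30, q0 = 10, q1 = 20,
                     blocks = data.frame(size = 10, dt = 0, dq = 0))
  comp2 <- compositeAlignment(c(chrR = refSeq),
                              c(q1 = paste0(q1, q2)),
                              list(toyChain(tSize = 40, t1 = 40,
                                            qName = "q1", qSize = 30,
                                            q1 = 30,
                                            blocks = data.frame(
                                              size = c(10, 20),
                                              dt = c(10, 0), dq = c(0, 0))),
                                   other2))
  expect_true("intra" %in% provenance(comp2)$class)
})

test_that("difference columns follow the positional compare rules", {
  mk <- function(r, q) new("CompositeAlignment", refGapped = r,
                           queryGapped = q,
                           provenance = data.frame(
                             start = 0, end = nchar(r), class = "syntenic",
                             chainId = 1, qName = "q", qStrand = "+"),
                           refName = "r")
  d <- differenceColumns(mk("ACGT", "ACGA"))
  expect_identical(d$refUnique, "---T")
  expect_identical(d$queryUnique, "---A")
  d2 <- differenceColumns(mk("ACGT", "ACGT"))
  expect_identical(d2$refUnique, "----")
  d3 <- differenceColumns(mk("AC-T", "ACGT"))
  expect_identical(d3$queryUnique, "--G-")
  expect_identical(d3$refUnique, "----")
  # case-insensitive equality
  d4 <- differenceColumns(mk("acgt", "ACGT"))
  expect_identical(d4$refUnique, "----")
})

test_that("identity counts case-insensitively and excludes N exchange", {
  mk <- function(r, q) new("CompositeAlignment", refGapped = r,
                           queryGapped = q,
                           provenance = data.frame(
                             start = 0, end = nchar(r), class = "syntenic",
                             chainId = 1, qName = "q", qStrand = "+"),
                           refName = "r")
  st <- alignmentStats(computeStats(mk("ACGTACGTAC", "ACGTACGTAT")))
  expect_equal(unname(st["identical"]), 9)
  expect_equal(unname(st["identityPct"]), 90)
  expect_equal(unname(st["identical"] + st["nonIdentical"]),
               unname(st["alignmentLength"]))
  stN <- alignmentStats(computeStats(mk("ANGT", "AAGT")))
  expect_equal(unname(stN["refNToQueryBp"]), 1)
  expect_equal(unname(stN["alignmentLength"]), 3)
  expect_equal(unname(stN["identical"]), 3)
  expect_equal(unname(stN["refLenNoN"]), 3)
  stQ <- alignmentStats(computeStats(mk("AAGT", "ANGT")))
  expect_equal(unname(stQ["queryNToRefBp"]), 1)
})

test_that("unique sequence is the query-uncovered reference", {
  set.seed(4)
  refSeq <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
  qrySeq <- paste0(substr(refSeq, 1, 10), substr(refSeq, 13, 30))
  comp <- compositeAlignment(c(chrR = refSeq), c(chrQ = qrySeq),
                             list(toyChain()))
  u <- uniqueSequence(comp)
  expect_identical(names(u), "chrR")
  expect_identical(as.character(u[[1]]), substr(refSeq, 11, 12))
  # full-coverage identical alignment -> empty unique contig
  full <- toyChain(tSize = 30, t1 = 30, qSize = 30, q1 = 30,
                   blocks = data.frame(size = 30, dt = 0, dq = 0))
  compF <- compositeAlignment(c(chrR = refSeq), c(chrQ = refSeq),
                              list(full))
  expect_equal(Biostrings::width(uniqueSequence(compF)), 0)
})

test_that("chain coverage profiles are monotone in k and split homologs", {
  ref <- c(chr1 = strrep("ACGT", 25), chr2 = strrep("GGCC", 25))
  mk <- function(t0, t1, q, score, id) toyChain(
    score = score, tName = "chr1", tSize = 100, t0 = t0, t1 = t1,
    qName = q, qSize = 100, q0 = 0, q1 = t1 - t0, id = id,
    blocks = data.frame(size = t1 - t0, dt = 0, dq = 0))
  chains <- list(mk(0, 15, "chr1", 900, 1),       # top chain: 15/100
                 mk(20, 30, "chr2A", 500, 2),
                 mk(40, 45, "chr9", 100, 3))
  prof <- chainCoverageProfile(chains, ref,
                               homologMap = c(chr2A = "chr1"))
  pk <- prof$perK[prof$perK$refName == "chr1", ]
  expect_equal(pk$coveredFrac[pk$k == 1], 0.15)
  expect_true(all(diff(pk$coveredBp) >= 0))        # k union is monotone
  expect_equal(pk$coveredBp[!is.finite(pk$k)], 30)
  h <- prof$homolog[prof$homolog$refName == "chr1", ]
  expect_equal(h$homologBp, 25)                    # chr1 + mapped chr2A
  expect_equal(h$nonHomologBp, 5)
  # chains on other contigs contribute nothing
  expect_equal(prof$perK$coveredBp[prof$perK$refName == "chr2"],
               rep(0, 4))
})

test_that("the four-column render tints difference columns by class", {
  set.seed(5)
  ref <- genGenome(1, 600, seed = 5)
  rec <- mutationRecipe(refLen = 600, nSnp = 3, inversions = 60,
                        translocations = 50, seed = 5)
  mc <- mutateAndChain(ref, rec)
  comp <- compositeAlignment(ref, mc$query, mc$chains,
                             refName = names(ref)[1])
  img <- renderAlignmentColumns(comp, rowWidth = 50, colGap = 2)
  expect_equal(dim(img)[2], 4 * 50 + 3 * 2)
  cols <- provenanceColors()
  expect_equal(cols$intra, c(180, 200, 255))       # blue-ish
  expect_equal(cols$inter, c(255, 180, 180))       # red-ish
  pv <- provenance(comp)
  ipos <- pv$start[pv$class == "intra"][1]         # a gapped position
  x <- ipos %% 50 + (2 - 1) * 52                   # column 2 pixel
  y <- ipos %/% 50
  d <- differenceColumns(comp)
  if (substr(d$refUnique, ipos + 1, ipos + 1) == "-")
    expect_equal(255 * img[y + 1, x + 1, ], cols$intra)
})
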