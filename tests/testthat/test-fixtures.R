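test_that("genome generation is byte-deterministic for a fixed seed", {
  f1 <- tmpfile(".fa"); f2 <- tmpfile(".fa")
  genGenome(2, c(800, 400), seed = 99, path = f1)
  genGenome(2, c(800, 400), seed = 99, path = f2)
  expect_identical(readBin(f1, "raw", 1e6), readBin(f2, "raw", 1e6))
  g3 <- genGenome(2, c(800, 400), seed = 100)
  expect_false(identical(as.character(g3[[1]]),
                         as.character(readFastaFile(f1)[[1]])))
})

test_that("regional GC content and planted repeats are honored", {
  g <- genGenome(1, 20000,
                 gcRegions = data.frame(contig = "chr1", start = 1,
                                        end = 10000, gc = 0.7),
                 tandemRepeats = data.frame(contig = "chr1", start = 15001,
                                            unit = "AAC", copies = 50),
                 seed = 12)
  s <- as.character(g[[1]])
  gcOf <- function(x) {
    ch <- strsplit(x, "")[[1]]
    mean(ch %in% c("G", "C"))
  }
  expect_equal(gcOf(substr(s, 1, 10000)), 0.7, tolerance = 0.03)
  expect_equal(gcOf(substr(s, 10001, 15000)), 0.41, tolerance = 0.03)
  expect_identical(substr(s, 15001, 15150), strrep("AAC", 50))
})

test_that("a null recipe yields one chain, full identity, no gaps", {
  ref <- genGenome(1, 1500, seed = 21)
  rec <- mutationRecipe(refLen = 1500, nSnp = 0, seed = 21)
  mc <- mutateAndChain(ref, rec)
  expect_length(mc$chains, 1)
  expect_equal(nrow(mc$chains[[1]]@blocks), 1)
  expect_identical(as.character(mc$query[["q1"]]),
                   as.character(ref[[1]]))
  gt <- mc$groundTruth
  expect_equal(unname(gt["identityPct"]), 100)
  expect_equal(unname(gt["refGapCount"] + gt["queryGapCount"]), 0)
  comp <- compositeAlignment(ref, mc$query, mc$chains)
  expect_equal(alignmentStats(computeStats(comp)), gt)
})

test_that("a 40 bp reference-side insertion becomes a dt=40 chain gap", {
  ref <- genGenome(1, 2000, seed = 22)
  rec <- mutationRecipe(refLen = 2000, nSnp = 0,
                        indels = data.frame(side = "ref", length = 40),
                        seed = 22)
  mc <- mutateAndChain(ref, rec)
  b <- mc$chains[[1]]@blocks
  expect_equal(sum(b$dt == 40), 1)
  expect_equal(sum(b$dq), 0)
  gt <- mc$groundTruth
  expect_equal(unname(gt["refGapsGt10"]), 1)
  expect_equal(unname(gt["refGapsGt100"]), 0)
  expect_equal(unname(gt["queryGapCount"]), 0)     # query side unaffected
  expect_equal(unname(gt["unalignedRef"]), 40)
})

test_that("inversions emit '-' strand chains composited as intra", {
  ref <- genGenome(1, 3000, seed = 23)
  rec <- mutationRecipe(refLen = 3000, nSnp = 0, inversions = 1000,
                        seed = 23)
  mc <- mutateAndChain(ref, rec)
  strands <- vapply(mc$chains, function(ch) ch@qStrand, character(1))
  expect_equal(sum(strands == "-"), 1)
  comp <- compositeAlignment(ref, mc$query, mc$chains)
  pv <- provenance(comp)
  expect_equal(sum(pv$end[pv$class == "intra"] -
                   pv$start[pv$class == "intra"]), 1000)
  # inverted segment still aligns identically after reverse-complement
  expect_equal(unname(alignmentStats(computeStats(comp))["identityPct"]),
               100)
  expect_identical(gsub("-", "", refGapped(comp)), as.character(ref[[1]]))
})

test_that("a known deletion in the query leaves exactly its unique bases", {
  ref <- genGenome(1, 4000, seed = 24)
  rec <- mutationRecipe(refLen = 4000, nSnp = 0,
                        indels = data.frame(side = "ref", length = 500),
                        seed = 24)
  mc <- mutateAndChain(ref, rec)
  comp <- compositeAlignment(ref, mc$query, mc$chains)
  expect_equal(unname(Biostrings::width(uniqueSequence(comp))), 500)
})

test_that("stats recovery holds across many random recipes", {
  ref <- genGenome(1, 2500, seed = 31)
  for (seed in 1:25) {
    rec <- randomRecipe(seed)
    mc <- mutateAndChain(ref, rec)
    comp <- compositeAlignment(ref, mc$query, mc$chains)
    expect_identical(gsub("-", "", refGapped(comp)),
                     as.character(ref[[1]]))
    expect_equal(alignmentStats(computeStats(comp)), mc$groundTruth,
                 info = paste("seed", seed))
    pv <- provenance(comp)
    expect_equal(pv$start[1], 0)
    expect_equal(pv$end[nrow(pv)], nchar(refGapped(comp)))
  }
})

test_that("the fixture dataset writer produces a coherent run input", {
  d <- tempfile()
  paths <- writeFixtureDataset(d, seed = 8)
  expect_true(all(file.exists(unlist(paths))))
  ref <- readFastaFile(paths$ref)
  qry <- readFastaFile(paths$query)
  chains <- readChainFile(paths$chain)
  comp <- compositeAlignment(ref, qry, chains)
  expect_identical(gsub("-", "", refGapped(comp)),
                   as.character(ref[[1]]))
})
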