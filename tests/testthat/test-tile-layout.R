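test_that("stride recurrence reproduces the default geometry", {
  tl <- tileLayout()
  expect_equal(strides(tl), c(1, 1, 103, 1009, 11000))
  expect_equal(capacity(tl), 100 * 1000 * 100 * 26 * 999)
  tl2 <- tileLayout(c(10, 10), c(0, 0))
  expect_equal(strides(tl2), c(1, 1))
  expect_error(tileLayout(c(10, 10), c(0, 0, 0)), "equal length")
  expect_error(tileLayout(c(0, 10), c(0, 0)), "positive")
})

test_that("forward map places rows, columns and mega-columns", {
  tl <- tileLayout()
  p <- indexToPixel(tl, c(0, 99, 100, 100000, 99999))
  expect_equal(p$x, c(0, 99, 0, 103, 99))
  expect_equal(p$y, c(0, 0, 1, 0, 999))
  expect_error(indexToPixel(tl, -1), "out of range")
  expect_error(indexToPixel(tl, capacity(tl)), "out of range")
})

test_that("inverse map returns NA in whitespace and inverts the forward map", {
  tl <- tileLayout()
  expect_equal(pixelToIndex(tl, 0, 0), 0)
  expect_true(is.na(pixelToIndex(tl, 101, 0)))   # 3 px column gap
  expect_true(is.na(pixelToIndex(tl, 102, 0)))
  expect_equal(pixelToIndex(tl, 103, 0), 100000)
  set.seed(42)
  ii <- floor(stats::runif(10000) * capacity(tl))
  p <- indexToPixel(tl, ii)
  expect_equal(pixelToIndex(tl, p$x, p$y), ii)
})

test_that("bijection holds exhaustively on a small custom layout", {
  tl <- tileLayout(c(10, 10, 4, 3), c(0, 0, 2, 3))
  ii <- seq_len(capacity(tl)) - 1
  p <- indexToPixel(tl, ii)
  key <- paste(p$x, p$y)
  expect_false(any(duplicated(key)))                   # injective
  expect_equal(pixelToIndex(tl, p$x, p$y), ii)         # inverse o forward
  # every canvas pixel either inverts exactly or is whitespace
  w <- max(p$x) + 1; h <- max(p$y) + 1
  grid <- expand.grid(x = 0:(w - 1), y = 0:(h - 1))
  idx <- pixelToIndex(tl, grid$x, grid$y)
  drawn <- !is.na(idx)
  expect_equal(sum(drawn), capacity(tl))
  f <- indexToPixel(tl, idx[drawn])
  expect_equal(f$x, grid$x[drawn])
  expect_equal(f$y, grid$y[drawn])
})

test_that("horizontal and vertical neighbors reflect 1D locality", {
  tl <- tileLayout()
  set.seed(7)
  i <- floor(stats::runif(500) * capacity(tl))
  i <- i[i %% 100 < 99]                      # not at a row end
  d <- indexToPixel(tl, i + 1)
  p <- indexToPixel(tl, i)
  expect_true(all(d$x - p$x == 1 & d$y - p$y == 0))
  # vertical neighbors inside a column differ by the column width
  j <- i[i %% 100000 < 99900]
  a <- indexToPixel(tl, j)
  b <- indexToPixel(tl, j + 100)
  expect_true(all(b$x == a$x & b$y == a$y + 1))
})

test_that("contigs start at column boundaries and jump mega-columns", {
  tl <- tileLayout()
  m <- placeContigs(c(a = strrep("A", 250), b = strrep("C", 50)), tl)
  expect_equal(contigEntries(m)$start, c(0, 100000))
  # descending-length placement on request
  m2 <- placeContigs(c(a = strrep("A", 50), b = strrep("C", 250)), tl,
                     sortContigs = TRUE)
  expect_equal(contigEntries(m2)$name, c("b", "a"))
  # a contig that cannot fit the remaining mega-column starts a fresh one
  megaCap <- 100000 * 100 * 26
  big1 <- strrep("A", megaCap - 100000)
  m3 <- placeContigs(c(x = big1, y = strrep("C", 200001)), tl)
  expect_equal(contigEntries(m3)$start[2], megaCap)
  small <- tileLayout(c(10, 10), c(0, 0))
  expect_error(placeContigs(c(z = strrep("A", 101)), small), "capacity")
})

test_that("snippets resolve pixels to sequence with 300 bp default", {
  tl <- tileLayout()
  ctg <- c(chr1 = paste(sample(c("A", "C", "G", "T"), 2000,
                               replace = TRUE), collapse = ""))
  m <- placeContigs(ctg, tl)
  p <- indexToPixel(tl, 999)
  sn <- extractSnippet(m, tl, ctg, p$x, p$y)
  expect_equal(sn$offset, 999)
  expect_equal(nchar(sn$seq), 300)
  expect_identical(sn$seq, substr(ctg[[1]], 1000, 1299))
  # truncation at contig end
  pEnd <- indexToPixel(tl, 1900)
  expect_equal(nchar(extractSnippet(m, tl, ctg, pEnd$x, pEnd$y)$seq), 100)
  # whitespace pixel gives NULL
  expect_null(extractSnippet(m, tl, ctg, 101, 0))
  # a short contig returns its whole tail
  m4 <- placeContigs(c(a = "ACGT"), tl)
  expect_identical(extractSnippet(m4, tl, c(a = "ACGT"), 0, 0)$seq, "ACGT")
})

test_that("custom layout strings parse to working layouts", {
  tl <- parseCustomLayout("[(100, 1000, 100, 26, 999), (0, 0, 3, 9, 700)]")
  expect_equal(strides(tl), strides(tileLayout()))
  expect_error(parseCustomLayout("[(10,10)]"), "custom layout")
})
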