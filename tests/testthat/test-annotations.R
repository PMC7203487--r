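test_that("flattening follows CDS > exon > mRNA > gene priority", {
  tl <- tileLayout(c(10, 20), c(0, 0))
  ctg <- c(chr1 = strrep("A", 150))
  m <- placeContigs(ctg, tl)
  feats <- makeFeatures("chr1", c("gene", "exon", "CDS"),
                        start = c(1, 10, 15), end = c(100, 30, 25))
  fl <- flattenFeatures(feats, m)
  codes <- as.character(fl$codes)
  expect_equal(codes[20], "CDS")
  expect_equal(codes[12], "exon")
  expect_equal(codes[5], "gene")
  expect_equal(codes[101], "none")
  # two overlapping genes still yield one code per base
  feats2 <- makeFeatures("chr1", c("gene", "gene"), c(1, 50), c(80, 120))
  expect_equal(unique(as.character(flattenFeatures(feats2, m)$codes[1:120])),
               "gene")
  expect_error(flattenFeatures(makeFeatures("chrX", "gene", 1, 5), m),
               "chrX")
})

test_that("flattening equals the brute-force per-base oracle", {
  tl <- tileLayout(c(10, 30, 4, 2), c(0, 0, 2, 3))
  for (seed in 1:20) {
    set.seed(seed)
    lens <- c(chr1 = 200, chr2 = 150)
    m <- placeContigs(c(chr1 = strrep("A", 200), chr2 = strrep("C", 150)),
                      tl)
    n <- sample(3:12, 1)
    sq <- sample(names(lens), n, replace = TRUE)
    st <- sapply(sq, function(s) sample(lens[[s]] - 20, 1))
    en <- pmin(st + sample(1:60, n, replace = TRUE), lens[sq])
    ty <- sample(c("gene", "mRNA", "exon", "CDS", "misc"), n, replace = TRUE)
    feats <- makeFeatures(sq, ty, st, en)
    got <- as.integer(flattenFeatures(feats, m)$codes) - 1L
    expect_equal(got, flattenOracle(feats, as.list(lens)))
  }
})

test_that("highlights lighten monotonically: exon > intron > plain", {
  tl <- tileLayout(c(10, 20), c(0, 0))
  ctg <- c(chr1 = strrep("G", 150))
  m <- placeContigs(ctg, tl)
  img <- renderRaster(m, tl, ctg)
  feats <- makeFeatures("chr1", c("gene", "exon"), c(1, 10), c(100, 30))
  hi <- overlayHighlights(img, tl, m, feats, role = "ref")
  pxOf <- function(i) {
    p <- indexToPixel(tl, i)
    c(hi[p$y + 1, p$x + 1, 1], hi[p$y + 1, p$x + 1, 2])
  }
  plain <- img[1, 1, ]
  intron <- hi[indexToPixel(tl, 4)$y + 1, indexToPixel(tl, 4)$x + 1, ]
  exon <- hi[indexToPixel(tl, 14)$y + 1, indexToPixel(tl, 14)$x + 1, ]
  un <- hi[indexToPixel(tl, 120)$y + 1, indexToPixel(tl, 120)$x + 1, ]
  expect_true(all(exon >= intron))
  expect_gt(sum(exon), sum(intron))          # exon strictly lighter
  expect_true(all(intron >= plain))
  expect_gt(sum(intron), sum(plain))
  expect_equal(un, plain)                    # unannotated untouched
  # overlapping genes blend twice (doubly highlighted)
  two <- makeFeatures("chr1", c("gene", "gene"), c(1, 1), c(50, 50))
  hi2 <- overlayHighlights(img, tl, m, two, role = "ref")
  hi1 <- overlayHighlights(img, tl, m, two[1], role = "ref")
  p5 <- indexToPixel(tl, 5)
  expect_gt(hi2[p5$y + 1, p5$x + 1, 1], hi1[p5$y + 1, p5$x + 1, 1])
})

test_that("repeat regions darken and query features get shadows", {
  tl <- tileLayout(c(10, 20), c(0, 0))
  ctg <- c(chr1 = strrep("A", 150))
  m <- placeContigs(ctg, tl)
  img <- renderRaster(m, tl, ctg)
  rep1 <- makeFeatures("chr1", "other", 20, 40)
  dk <- overlayHighlights(img, tl, m, rep1, role = "repeat")
  expect_true(all(dk <= img + 1e-12))
  p <- indexToPixel(tl, 25)
  expect_lt(dk[p$y + 1, p$x + 1, 2], img[p$y + 1, p$x + 1, 2])
  q <- makeFeatures("chr1", "gene", 45, 55)
  sh <- overlayHighlights(img, tl, m, q, role = "query")
  expect_false(identical(sh, img))           # shadow ink present
})

test_that("the annotation track interlaces colored columns and labels", {
  tl <- tileLayout(c(10, 10, 3, 2), c(0, 0, 2, 3))
  ctg <- c(chr1 = strrep("A", 250))
  m <- placeContigs(ctg, tl)
  img <- renderRaster(m, tl, ctg)
  feats <- makeFeatures("chr1", c("gene", "mRNA", "exon", "CDS"),
                        c(1, 1, 10, 15), c(240, 240, 60, 25),
                        label = c("G1", "", "", ""))
  tr <- buildAnnotationTrack(img, tl, m, feats, annotationWidth = 2,
                             gap = 1, drawLabels = FALSE)
  ins <- 3                                   # annotationWidth + gap
  expect_equal(dim(tr)[2], dim(img)[2] + 3 * ins)  # 3 occupied columns
  tcol <- annotationTrackColors()
  px <- function(x, y) 255 * tr[y + 1, x + 1, ]
  # column 0 track sits at x = 0,1; its row r covers bases r*10+1..r*10+10
  expect_equal(px(0, 1), tcol$CDS)           # row 1, bin 1: bases 11-15
  expect_equal(px(0, 3), tcol$exon)          # row 3: bases 31-40, exon
  expect_equal(px(0, 7), tcol$mRNA)          # intron row -> orange
  # column 2 track (rank 3) at x = 24 + 2*ins; row 4 = bases 241-250
  expect_equal(px(24 + 2 * ins, 4), tcol$none)     # past the gene
  # width-1 track columns work
  tr1 <- buildAnnotationTrack(img, tl, m, feats, annotationWidth = 1,
                              gap = 0, drawLabels = FALSE)
  expect_equal(dim(tr1)[2], dim(img)[2] + 3)
  # a gene spanning 3 columns labels the middle one
  expect_equal(labelColumnOf(0, 299, 100), 1)
  expect_equal(labelColumnOf(0, 99, 100), 0)
})

test_that("label placement: strand anchors, centroids, size monotone", {
  tl <- tileLayout(c(10, 30), c(0, 0))
  ctg <- c(chr1 = strrep("A", 300))
  m <- placeContigs(ctg, tl)
  feats <- makeFeatures("chr1", c("gene", "gene"), c(1, 101), c(100, 200),
                        strand = c("+", "-"), label = c("PLUS", "MINUS"))
  lb <- placeLabels(feats, m, tl)
  expect_equal(lb$anchor, c("top", "bottom"))
  expect_equal(lb$x1 - lb$x0 + 1, c(10, 10))  # first column segment width
  # ideogram: centroid of the mapped pixels
  pl <- peanoLayout(c(3, 3, 3), c(5, 3, 3))
  mp <- placeContigs(c(chr1 = strrep("A", 300)), tl)   # map reused for span
  g1 <- makeFeatures("chr1", "gene", 1, 100, label = "BLOB")
  lbI <- placeLabels(g1, mp, pl)
  p <- indexToPixel(pl, 0:99)
  expect_equal(lbI$x0, min(p$x))
  expect_equal(lbI$y1, max(p$y))
  # larger bbox area never shrinks the font
  a <- labelStyle(c(1e3, 1e4, 1e6, 1e8))
  expect_true(all(diff(a$size) >= 0))
  expect_true(all(diff(a$opacity) <= 0))
})
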