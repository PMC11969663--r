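test_that("windowing tiles each chromosome exactly", {
  w <- windowGenome(c(a = 1500L), 500L)
  expect_equal(length(w), 3L)
  expect_true(all(width(w) == 500L))
  w2 <- windowGenome(c(a = 1600L), 500L)
  expect_equal(length(w2), 4L)
  expect_equal(width(w2)[4], 100L)
  # union equals the genome span; pairwise overlaps are empty
  w3 <- windowGenome(c(a = 1600L, b = 777L), 500L)
  expect_equal(sum(width(w3)), 1600L + 777L)
  expect_equal(sum(width(GenomicRanges::reduce(w3))), 1600L + 777L)
  expect_true(all(GenomicRanges::countOverlaps(w3, w3) == 1L))
  expect_equal(length(windowGenome(character(0), 500L)), 0L)
  expect_error(windowGenome(c(a = 100L), 0), "positive")
})

test_that("alignment identity behaves as a full-span identity", {
  set.seed(10)
  s <- randSeq(500)
  expect_equal(alignmentIdentity(s, s), 1)
  a <- randSeq(2000)
  b <- ripscope:::mutateToIdentity(a, 0.974)
  expect_lt(abs(alignmentIdentity(a, b) - 0.974), 0.003)
  expect_equal(alignmentIdentity(a, b), alignmentIdentity(b, a))
  expect_error(alignmentIdentity("", s), "non-empty")
  # unrelated sequences score near the random expectation, far below the
  # duplicate cutoff
  ids <- replicate(300, alignmentIdentity(randSeq(500), randSeq(500)))
  expect_gte(mean(ids < 0.65), 0.99)
})

test_that("planted duplicates are recovered and sub-cutoff pairs are not", {
  cfg <- simConfig(c(c1 = 100000L, c2 = 100000L), list(
    duplicateSpec("hi", "dispersed-pair", chrom = c("c1", "c2"),
                  start = c(20017L, 50233L), copyLength = 1500L,
                  identity = 0.90),
    duplicateSpec("lo", "dispersed-pair", chrom = c("c1", "c2"),
                  start = c(60011L, 20011L), copyLength = 1500L,
                  identity = 0.60)), seed = 8L)
  par <- buildParentalGenomes(cfg, seed = 8L)
  pairs <- findDuplicatePairs(parentGenome(par, 1))
  expect_gt(nrow(pairs), 0L)
  win <- windowGenome(parentGenome(par, 1))
  ann <- annotateDupWindows(win, pairs)
  dup <- ann$windows[ann$windows$dup]
  # every window overlapping either copy of the 90% family is Dup
  hi <- GRanges(c("c1", "c2"), IRanges(c(20017L, 50233L), width = 1500L))
  expect_true(all(overlapsAny(win[overlapsAny(win, hi)], dup)))
  # no Dup window touches the 60% family
  lo <- GRanges(c("c1", "c2"), IRanges(c(60011L, 20011L), width = 1500L))
  expect_false(any(overlapsAny(dup, lo)))
  expect_true(all(pairs$identity > 0.65))
})

test_that("inverted duplicates are detected", {
  set.seed(77)
  copy <- randSeq(1200)
  rc <- paste(rev(chartr("ACGT", "TGCA", strsplit(copy, "")[[1]])),
              collapse = "")
  bg1 <- randSeq(20000); bg2 <- randSeq(20000)
  chrom <- paste0(bg1, copy, randSeq(5000), rc, bg2)
  pairs <- findDuplicatePairs(c(chr = chrom))
  expect_gt(nrow(pairs), 0L)
  expect_true(all(pairs$orient == "-"))
  expect_true(any(pairs$startA <= 21200 & pairs$endA >= 20001))
})

test_that("Dup annotation is idempotent and order-independent", {
  win <- windowGenome(c(a = 5000L), 500L)
  pairs <- data.frame(chromA = "a", startA = c(1001L, 3001L),
                      endA = c(1500L, 3500L), chromB = "a",
                      startB = c(4001L, 1001L), endB = c(4500L, 1500L),
                      identity = 0.9, orient = "+",
                      gap = NA, category = "lt5kb")
  a1 <- annotateDupWindows(win, pairs)
  a2 <- annotateDupWindows(win, pairs[2:1, ])
  expect_identical(a1$dupSpan, a2$dupSpan)
  expect_identical(mcols(a1$windows)$dup, mcols(a2$windows)$dup)
  expect_equal(a1$dupSpan, 1500L)  # windows 3, 7, 9
  none <- annotateDupWindows(win, pairs[0, ])
  expect_equal(none$dupSpan, 0L)
  expect_false(any(mcols(none$windows)$dup))
  one <- annotateDupWindows(win, pairs[1, ])
  expect_equal(which(mcols(one$windows)$dup), c(3L, 9L))
})

test_that("distance categories partition pairs with inclusive lower bounds", {
  mk <- function(chromB, startB) data.frame(
    chromA = "c1", startA = 1001L, endA = 1500L,
    chromB = chromB, startB = startB, endB = startB + 499L)
  expect_equal(categorizeDistance(mk("c1", 4501L))$category, "lt5kb")
  expect_equal(categorizeDistance(mk("c1", 4501L))$gap, 3000)
  expect_equal(categorizeDistance(mk("c2", 4501L))$category,
               "interchromosomal")
  expect_equal(categorizeDistance(mk("c1", 6501L))$category, "kb5to300")
  expect_equal(categorizeDistance(mk("c1", 6501L))$gap, 5000)
  expect_equal(categorizeDistance(mk("c1", 400000L))$category, "gt300kb")
  # overlapping features: gap 0, nearest category
  expect_equal(categorizeDistance(mk("c1", 1200L))$category, "lt5kb")
  expect_equal(categorizeDistance(mk("c1", 1200L))$gap, 0)
  # partition: each pair receives exactly one category
  many <- do.call(rbind, list(mk("c1", 2001L), mk("c2", 2001L),
                              mk("c1", 350000L)))
  cats <- categorizeDistance(many)$category
  expect_equal(length(cats), 3L)
  expect_true(all(cats %in% c("lt5kb", "kb5to300", "gt300kb",
                              "interchromosomal")))
})
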