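test_that("window levels implement the count formula exactly", {
  counts <- data.frame(chrom = "c1", pos = c(10L, 20L, 150L, 260L),
                       strand = c("+", "-", "+", "+"),
                       meth = c(5L, 0L, 3L, 0L),
                       unmeth = c(5L, 10L, 0L, 7L))
  w <- windowLevels(counts, 100L, c(c1 = 400L))
  expect_equal(nrow(w), 4L)
  expect_equal(w$level[1], 5 / 20)       # strands pooled
  expect_equal(w$level[2], 1.0)
  expect_equal(w$level[3], 0.0)
  expect_true(is.na(w$level[4]))         # zero coverage is missing
  expect_equal(w$level[!is.na(w$level)],
               (w$meth / (w$meth + w$unmeth))[!is.na(w$level)])
  # summing two count tables then windowing equals windowing then summing
  c2 <- transform(counts, meth = c(1L, 2L, 0L, 4L))
  wSum <- windowLevels(rbind(counts, c2), 100L, c(c1 = 400L))
  expect_equal(wSum$meth, w$meth + windowLevels(c2, 100L, c(c1 = 400L))$meth)
})

test_that("relative change uses the WT inclusion floor", {
  wt <- data.frame(chrom = "c1", start = c(1L, 101L, 201L),
                   end = c(100L, 200L, 300L), meth = 1L, unmeth = 1L,
                   coverage = 2L, level = c(0.3, 0.05, 0.2))
  mut <- transform(wt, level = c(0.0, 0.5, 0.2))
  ch <- relativeChange(mut, wt, minWT = 0.1)
  expect_equal(nrow(ch), 2L)             # the 0.05 window is excluded
  expect_equal(ch$change[ch$start == 1L], -1.0)
  expect_equal(ch$change[ch$start == 201L], 0.0)
  expect_error(relativeChange(mut[-1, ], wt), "grids differ")
})

test_that("change histograms bin completely with a dedicated loss bin", {
  h0 <- changeHistogram(rep(0, 40), binWidth = 0.05)
  expect_equal(sum(h0$count), 40L)
  expect_equal(h0$count[h0$binLow <= 0 & h0$binHigh > 0], 40L)
  x <- c(rep(-1, 7), rep(0, 43))
  h <- changeHistogram(x, binWidth = 0.05)
  expect_equal(h$count[h$label == "complete-loss"], 7L)
  expect_equal(sum(h$count), 50L)
  expect_error(changeHistogram(x, binWidth = 0), "positive")
})

test_that("loss profiles separate localized loss from global shifts", {
  localized <- c(rep(-1, 27), rep(0, 173))      # 13.5% fully dependent
  resL <- classifyLossProfile(localized)
  expect_equal(resL$profile, "localized-loss")
  expect_equal(resL$dependentFraction, 0.135)
  uniform <- rep(-0.25, 200)
  expect_equal(classifyLossProfile(uniform)$profile, "global-shift")
  expect_equal(classifyLossProfile(rep(0, 50))$profile, "no-change")
  expect_error(classifyLossProfile(rep(0, 5)), "at least")
})

test_that("simulated methylomes reproduce the state-machine targets", {
  par <- fixtureParents()
  # first-generation transitional heterochromatin on the young duplicate
  w1 <- simulateLineage(par, 1, seed = 13)
  m1 <- measureLineageMethylation(w1, depth = 40, seed = 13)
  se <- sqrt(0.33 * 0.67 / (m1$nCytosines * 40))
  expect_lt(abs(m1$level - 0.33), 5 * se + 0.002)
  # generational ordering of vegetative hda-1 knockouts:
  # W1ko << W2ko ~ W3ko < W4ko
  ko <- vapply(1:4, function(g)
    measureLineageMethylation(simulateLineage(par, g, seed = 13), "hda-1",
                              seed = 13)$level, numeric(1))
  expect_lt(ko[1], 0.02)
  expect_gt(ko[2], ko[1]); expect_gt(ko[3], ko[1])
  expect_gt(ko[4], ko[2]); expect_gt(ko[4], ko[3])
  expect_lt(abs(ko[2] - ko[3]), 0.05)
  # an hda-1-null lineage never establishes methylation while its AT
  # fraction keeps rising
  h <- simulateLineage(par, 4, "hda-1", seed = 13)
  tr <- lineageTrajectory(h)
  expect_true(all(tr$target < 0.02))
  expect_gt(tr$atFraction[4], tr$atFraction[1])
  expect_lt(measureLineageMethylation(h, seed = 13)$level, 0.02)
})
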