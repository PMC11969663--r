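test_that("RIP classification is the strand-symmetric G:C->A:T rule", {
  expect_true(classifyRip("C", "T"))
  expect_true(classifyRip("G", "A"))
  expect_false(classifyRip("A", "G"))
  expect_false(classifyRip("C", "A"))
  expect_equal(classifyRip(c("C", "G", "T"), c("T", "A", "C")),
               c(TRUE, TRUE, FALSE))
  expect_error(classifyRip("N", "T"), "A/C/G/T")
})

test_that("rates are count / span / samples and additive over regions", {
  muts <- data.frame(chrom = "c1", pos = seq_len(100) * 10L,
                     ref = "C", alt = "T")
  regions <- GRanges("c1", IRanges(1, 2e6))
  expect_equal(ripRate(muts, regions, 10), 5.0)
  expect_equal(ripRate(muts[0, ], regions, 10), 0.0)
  # non-RIP mutations are not counted
  mutsX <- transform(muts, alt = "G")
  expect_equal(ripRate(mutsX, regions, 10), 0.0)
  # additivity over disjoint region sets, invariance to ordering
  r1 <- GRanges("c1", IRanges(1, 500))
  r2 <- GRanges("c1", IRanges(501, 1010))
  both <- c(r1, r2)
  cnt <- function(r) ripRate(muts, r, 1) * sum(width(reduce(r))) / 1e6
  expect_equal(cnt(both), cnt(r1) + cnt(r2))
  expect_equal(ripRate(muts, both, 3), ripRate(muts, rev(both), 3))
  expect_error(ripRate(muts, regions, 0), "positive")
  expect_error(ripRate(muts, GRanges(), 5), "span")
})

test_that("reduction percentages follow the sign convention", {
  expect_equal(reductionPct(1.0, 0.321), 67.9)
  expect_equal(reductionPct(1.0, 0.0), 100.0)
  expect_equal(reductionPct(1.0, 1.2), -20.0)
  expect_error(reductionPct(0, 1), "positive")
})

test_that("methylation stratification splits the duplicate span at the
           threshold", {
  dup <- GRanges("c1", IRanges(c(1, 2001), c(1000, 3000)))
  methW <- GRanges("c1", IRanges(c(1, 2001), c(1000, 3000)))
  methW$level <- c(0.4, 0.05)
  highMuts <- data.frame(chrom = "c1", pos = c(10L, 500L, 900L),
                         ref = "C", alt = "T")
  res <- stratifyByParentalMethylation(highMuts, methW, dup, nSamples = 2)
  expect_equal(res$highFraction, 1.0)
  expect_equal(res$table$spanMb, c(0.001, 0.001))
  # rate * span * samples = count, exactly
  expect_equal(res$table$rate * res$table$spanMb * res$table$nSamples,
               res$table$count)
  # threshold 1.0 puts everything in the low stratum
  res2 <- stratifyByParentalMethylation(highMuts, methW, dup, threshold = 1)
  expect_equal(res2$highFraction, 0)
  # "exceeds" is strict: a window exactly at the threshold is low
  methW$level <- c(0.10, 0.05)
  res3 <- stratifyByParentalMethylation(highMuts, methW, dup,
                                        threshold = 0.10)
  expect_equal(res3$highFraction, 0)
  expect_error(stratifyByParentalMethylation(highMuts, methW, GRanges()),
               "span")
})

test_that("distance-category counting counts each pair instance", {
  pairs <- data.frame(
    chromA = c("c1", "c1"), startA = c(1L, 1L), endA = c(500L, 500L),
    chromB = c("c1", "c2"), startB = c(10501L, 1L), endB = c(11000L, 500L),
    identity = 0.9, orient = "+", gap = c(10000, NA),
    category = c("kb5to300", "interchromosomal"))
  muts <- data.frame(chrom = "c1", pos = c(10L, 20L, 30L), ref = "C",
                     alt = "T")
  tab <- ratesByDistanceCategory(muts, pairs)
  # the shared window c1:1-500 belongs to both pairs: 3 counts each
  expect_equal(tab$count[tab$category == "kb5to300"], 3L)
  expect_equal(tab$count[tab$category == "interchromosomal"], 3L)
  # a mutation in only one pair's window counts once
  muts2 <- data.frame(chrom = "c1", pos = 10700L, ref = "G", alt = "A")
  tab2 <- ratesByDistanceCategory(muts2, pairs)
  expect_equal(tab2$count[tab2$category == "kb5to300"], 1L)
  expect_equal(tab2$count[tab2$category == "interchromosomal"], 0L)
  expect_equal(nrow(ratesByDistanceCategory(muts, pairs[0, ])), 0L)
})

test_that("per-site rates match the worked LexAO arithmetic", {
  r <- perSiteRate(20, 92, 1000)
  expect_equal(r, 20 / 92000)
  expect_equal(signif(r, 2), 2.2e-4)
  expect_equal(perSiteRate(0, 76, 1000), 0)
  expect_equal(perSiteRate(7, 1, 1), 7)
  expect_error(perSiteRate(5, 0, 1000), "positive")
  expect_error(perSiteRate(-1, 10, 1000), "nonnegative")
})

test_that("Brunner-Munzel matches a direct relative-effect computation and
           its exchangeability/symmetry contracts", {
  set.seed(5)
  x <- rnorm(12); y <- rnorm(15, 0.8)
  bm <- brunnerMunzel(x, y)
  # independent route to the relative effect: direct enumeration
  direct <- mean(outer(x, y, "<") + 0.5 * outer(x, y, "=="))
  expect_equal(bm$estimate, direct)
  # identical multisets: relative effect 1/2, p = 1
  same <- brunnerMunzel(x, x)
  expect_equal(same$estimate, 0.5)
  expect_equal(same$p.value, 1)
  # swap symmetry
  sw <- brunnerMunzel(y, x)
  expect_equal(sw$estimate, 1 - bm$estimate)
  expect_equal(sw$p.value, bm$p.value)
  # invariance under strictly monotone transforms of the pooled data
  tr <- brunnerMunzel(exp(x), exp(y))
  expect_equal(tr$statistic, bm$statistic)
  expect_equal(tr$p.value, bm$p.value)
  expect_error(brunnerMunzel(1, y), "at least 2")
})

test_that("the t approximation agrees with the permutation distribution at
           moderate sample sizes", {
  set.seed(9)
  for (sh in c(0, 0.7)) {
    x <- rnorm(25); y <- rnorm(25, sh)
    pt_ <- brunnerMunzel(x, y)$p.value
    pp <- brunnerMunzelPermutation(x, y, maxPermutations = 20000L,
                                   seed = 4)$p.value
    expect_lt(abs(pt_ - pp), 0.02)
  }
})
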