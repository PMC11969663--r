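test_that("parental genomes realise the planted duplicate targets", {
  par <- fixtureParents()
  g1 <- as.character(parentGenome(par, 1))
  g2 <- as.character(parentGenome(par, 2))
  ann <- as.data.frame(duplicateAnnotation(par))

  # unlinked transposon pair: realized identity at the configured target
  a <- substring(g1[["chrI"]], 20001, 31000)
  b <- substring(g2[["chrII"]], 20001, 31000)
  expect_lt(abs(alignmentIdentity(a, b) - 0.974), 0.005)

  # copy A only in parent 1, copy B only in parent 2: the other parent
  # holds unrelated background at the locus
  expect_lt(alignmentIdentity(a, substring(g2[["chrI"]], 20001, 31000)), 0.6)
  expect_lt(alignmentIdentity(b, substring(g1[["chrII"]], 20001, 31000)), 0.6)

  # R-L-R cassette composition close to its AT target
  rlr <- ann[ann$family == "RLR", ]
  cassette <- substring(g1[["chrI"]], min(rlr$start), max(rlr$end))
  at <- mean(strsplit(cassette, "")[[1]] %in% c("A", "T"))
  expect_lt(abs(at - 0.4564), 0.005)
  expect_equal(rlr$end[rlr$copy == "R1"] - rlr$start[rlr$copy == "R1"] + 1L,
               802L)
  expect_equal(rlr$end[rlr$copy == "L"] - rlr$start[rlr$copy == "L"] + 1L,
               729L)

  # dispersed pairs present identically in both parents
  het <- ann[ann$family == "hetA" & ann$copy == "A", ]
  expect_identical(substring(g1[[het$seqnames]], het$start, het$end),
                   substring(g2[[het$seqnames]], het$start, het$end))
})

test_that("invalid placements and unreachable identities are rejected", {
  overl <- simConfig(c(chr = 5000L), list(
    duplicateSpec("x", "dispersed-pair", chrom = c("chr", "chr"),
                  start = c(1L, 500L), copyLength = 1000L, identity = 0.9)))
  expect_error(buildParentalGenomes(overl, seed = 1), "overlap")
  outside <- simConfig(c(chr = 5000L), list(
    duplicateSpec("x", "dispersed-pair", chrom = c("chr", "chr"),
                  start = c(1L, 4500L), copyLength = 1000L, identity = 0.9)))
  expect_error(buildParentalGenomes(outside, seed = 1), "beyond")
  unreach <- simConfig(c(chr = 5000L), list(
    duplicateSpec("x", "dispersed-pair", chrom = c("chr", "chr"),
                  start = c(1L, 2000L), copyLength = 20L, identity = 0.99)))
  expect_error(buildParentalGenomes(unreach, seed = 1), "unreachable")
})

test_that("an empty duplicate list yields two clean background genomes", {
  cfg <- simConfig(c(c1 = 60000L, c2 = 60000L), list(), seed = 5L)
  par <- buildParentalGenomes(cfg, seed = 5L)
  expect_identical(as.character(parentGenome(par, 1)),
                   as.character(parentGenome(par, 2)))
  pairs <- findDuplicatePairs(parentGenome(par, 1))
  expect_equal(nrow(pairs), 0L)
})

test_that("expected RIP intensity decomposes by genotype", {
  m <- defaultIntensityModel()
  co <- intensityCoefficients(m)
  for (cl in chromatinClasses(m)) {
    expect_equal(expectedRipIntensity(cl, character(), m), sum(co[cl, ]))
    expect_equal(expectedRipIntensity(cl, c("rid", "dim-2"), m), 0)
    # monotone: wild type >= single knockout >= double knockout
    wt <- expectedRipIntensity(cl, character(), m)
    expect_lte(expectedRipIntensity(cl, "rid", m), wt)
    expect_lte(expectedRipIntensity(cl, "dim-2", m), wt)
  }
  # calibrated single-knockout residuals for heterochromatic duplicates
  wtHet <- expectedRipIntensity("constitutive", model = m)
  expect_equal(reductionPct(wtHet, expectedRipIntensity("constitutive",
                                                        "rid", m)),
               67.9, tolerance = 0.001)
  expect_equal(reductionPct(wtHet, expectedRipIntensity("constitutive",
                                                        "dim-2", m)),
               81.8, tolerance = 0.001)
  # the linker is entirely synergistic: either knockout silences it
  expect_equal(expectedRipIntensity("linker", "dim-2", m), 0)
  expect_equal(expectedRipIntensity("linker", "rid", m), 0)
  expect_error(expectedRipIntensity("plasmid", character(), m), "unknown")
})

test_that("clustered mutation placement is G:C->A:T and clustered", {
  set.seed(99)
  seqc <- randSeq(10000)
  mu <- placeClusteredMutations(seqc, 50, seed = 7)
  expect_equal(nrow(mu), 50L)
  expect_true(all((mu$ref == "C" & mu$alt == "T") |
                  (mu$ref == "G" & mu$alt == "A")))
  expect_false(any(duplicated(mu$pos)))
  expect_identical(substring(seqc, mu$pos, mu$pos), mu$ref)
  expect_equal(nrow(placeClusteredMutations(seqc, 0)), 0L)
  expect_error(placeClusteredMutations("ATATATACGAT", 5), "short by")

  # nearest-neighbour distances are tighter than uniform placement over
  # the same G:C sites (uniform oracle, matched n, 200 replicates)
  gc <- which(strsplit(seqc, "")[[1]] %in% c("G", "C"))
  nn <- function(p) mean(diff(sort(p)))
  set.seed(1)
  clustered <- replicate(200, nn(placeClusteredMutations(seqc, 50)$pos))
  uniform <- replicate(200, nn(sample(gc, 50)))
  expect_lt(mean(clustered), mean(uniform))
})

test_that("the chromatin state machine follows the transition table", {
  # establishment on a RIPed euchromatic copy
  st <- evolveChromatin("euchromatic", character(), 1, TRUE)
  expect_equal(st, list(state = "transitional", target = 0.33))
  # no event, or no RID: no establishment
  expect_equal(evolveChromatin("euchromatic", character(), 1, FALSE)$state,
               "euchromatic")
  expect_equal(evolveChromatin("euchromatic", "rid", 1, TRUE)$state,
               "euchromatic")
  # hda-1 absent blocks establishment
  h <- evolveChromatin("euchromatic", "hda-1", 1, TRUE)
  expect_equal(h$state, "silenced-null")
  expect_lt(h$target, 0.02)
  # hda-2 / hda-3 absent: reduced establishment targets
  expect_equal(evolveChromatin("euchromatic", "hda-2", 1, TRUE)$target, 0.14)
  expect_equal(evolveChromatin("euchromatic", "hda-3", 1, TRUE)$target, 0.10)
  # maturation and maintenance
  m <- evolveChromatin("transitional", character(), 2, FALSE)
  expect_equal(m$state, "constitutive")
  expect_equal(evolveChromatin("constitutive", character(), 3, FALSE,
                               level = 0.41)$target, 0.41)
  # vegetative knockouts of established states
  expect_equal(knockoutChromatin("constitutive", 2, "hda-1"), 0.163)
  expect_equal(knockoutChromatin("constitutive", 4, "hda-1"), 0.225)
  expect_equal(knockoutChromatin("constitutive", 2, "dim-2"), 0)
  expect_equal(knockoutChromatin("constitutive", 2, "hda-2", level = 0.4),
               0.3)
  expect_error(evolveChromatin("plasmid", character(), 1, TRUE), "unknown")
  expect_error(evolveChromatin("euchromatic", "xyz-9", 1, TRUE), "unknown")
})

test_that("cross simulation respects genotype nulls and edge cases", {
  par <- fixtureParents()
  expect_error(simulateCross(par, nTetrads = -1), "nonnegative")
  empty <- simulateCross(par, nTetrads = 0, seed = 1)
  expect_equal(nSpores(empty), 0L)
  expect_equal(nrow(truthMutations(empty)), 0L)
  dko <- simulateCross(par, c("rid", "dim-2"), nTetrads = 5, seed = 3)
  expect_equal(nrow(truthMutations(dko)), 0L)
})

test_that("cross simulation is deterministic and mutation-conserving", {
  par <- fixtureParents()
  c1 <- simulateCross(par, nTetrads = 2, seed = 11)
  c2 <- simulateCross(par, nTetrads = 2, seed = 11)
  expect_identical(truthMutations(c1), truthMutations(c2))
  f1 <- tempfile(fileext = ".vcf"); f2 <- tempfile(fileext = ".vcf")
  writeVcfTable(truthMutations(c1), f1)
  writeVcfTable(truthMutations(c2), f2)
  expect_identical(readLines(f1), readLines(f2))

  # every truth mutation is recoverable by direct sequence diff against
  # the parent of origin, and chromosomes segregate 2:2 within a tetrad
  sp <- sporeInfo(c1)[[1]]
  gs <- as.character(sporeGenome(c1, 1))
  for (ch in names(gs)) {
    parent <- as.character(parentGenome(par, sp$origin[[ch]]))[[ch]]
    va <- strsplit(gs[[ch]], "")[[1]]
    vp <- strsplit(parent, "")[[1]]
    diffs <- which(va != vp)
    tr <- truthMutations(c1)
    tr <- tr[tr$spore == 1 & tr$chrom == ch, ]
    expect_setequal(diffs, tr$pos)
    expect_identical(va[tr$pos], tr$alt)
    expect_identical(vp[tr$pos], tr$ref)
  }
  origins <- vapply(sporeInfo(c1)[1:4], function(s) s$origin[["chrI"]], "")
  expect_equal(sum(origins == "p1"), 2L)
})

test_that("emitted observables honour depth, error and dim-2 contracts", {
  par <- fixtureParents()
  region <- GRanges("chrI", IRanges(60001, 72000))

  # dim-2-null: every emitted methylated count is zero
  d2 <- simulateCross(par, "dim-2", nTetrads = 1, seed = 5)
  obs <- emitObservables(d2, 1, seed = 2, regions = region)
  expect_true(all(obs$bisulfite$meth == 0L))

  # noiseless pileups of a mutation-free spore carry only the spore allele
  dko <- simulateCross(par, c("rid", "dim-2"), nTetrads = 1, seed = 5)
  clean <- emitObservables(dko, 1, errorRate = 0, seed = 2, regions = region)
  gs <- as.character(sporeGenome(dko, 1))
  v <- strsplit(gs[["chrI"]], "")[[1]]
  p <- clean$pileup
  tot <- cbind(p$A_plus + p$A_minus, p$C_plus + p$C_minus,
               p$G_plus + p$G_minus, p$T_plus + p$T_minus)
  supported <- rowSums(tot > 0)
  expect_true(all(supported <= 1))
  nz <- which(rowSums(tot) > 0)
  expect_identical(c("A", "C", "G", "T")[max.col(tot[nz, ])], v[p$pos[nz]])

  # mean depth within 5% of the requested 40x over >= 10 kb
  expect_lt(abs(mean(rowSums(tot)) - 40) / 40, 0.05)
  expect_error(emitObservables(d2, 1, depth = -1), "depth")
  expect_error(emitObservables(d2, 1, errorRate = 0.7), "errorRate")
})
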