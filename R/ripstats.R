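# RIP classification and rate statistics: per-sample per-Mb rates,
# genotype reduction percentages, methylation- and distance-stratified
# summaries, per-site rates, and the Brunner-Munzel rank test.

#' Classify a substitution as RIP-type
#'
#' RIP introduces G:C->A:T transitions; the classification is
#' strand-symmetric: C->T and G->A are RIP, everything else is not.
#'
#' @param ref,alt Single reference/alternate bases (vectorised).
#' @return Logical vector.
#' @export
classifyRip <- function(ref, alt) {
  if (any(!ref %in% .BASES) || any(!alt %in% .BASES))
    stop("ref and alt must be single A/C/G/T bases")
  (ref == "C" & alt == "T") | (ref == "G" & alt == "A")
}

## mutations (chrom/pos data.frame) overlapping a GRanges region set
mutationsInRegions <- function(mutations, regions) {
  if (nrow(mutations) == 0L) return(mutations[0, , drop = FALSE])
  gr <- GRanges(mutations$chrom, IRanges(mutations$pos, mutations$pos))
  mutations[suppressWarnings(overlapsAny(gr, regions)), , drop = FALSE]
}

#' Per-sample per-Mb RIP mutation rate over a region set
#'
#' Counts RIP-classified mutations overlapping the regions and divides by
#' the region span in Mb and by the number of samples.
#'
#' @param mutations data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @param regions `GRanges` region set (overlapping ranges are reduced
#'   before the span is measured).
#' @param nSamples Number of samples the mutations were pooled from.
#' @return Rate in mutations per sample per Mb.
#' @export
ripRate <- function(mutations, regions, nSamples) {
  if (nSamples <= 0) stop("nSamples must be positive")
  span <- sum(width(reduce(regions)))
  if (span <= 0) stop("region span must be positive")
  m <- mutationsInRegions(mutations, regions)
  n <- if (nrow(m)) sum(classifyRip(m$ref, m$alt)) else 0L
  n / (span / 1e6) / nSamples
}

#' Percent reduction of a knockout rate relative to wild type
#'
#' @param rateWT Wild-type rate (> 0).
#' @param rateKO Knockout rate.
#' @return `(1 - rateKO / rateWT) * 100`; an increase comes out negative.
#' @export
reductionPct <- function(rateWT, rateKO) {
  if (rateWT <= 0) stop("wild-type rate must be positive for a reduction")
  (1 - rateKO / rateWT) * 100
}

#' Stratify RIP mutations by parental methylation of the duplicate span
#'
#' Splits the duplicate span into a high stratum (parental methylation
#' level strictly greater than `threshold`) and a low stratum, and
#' reports spans, counts, per-sample-per-Mb rates and the fraction of all
#' RIP mutations falling in the high stratum.
#'
#' @param mutations Mutation data.frame (`chrom`, `pos`, `ref`, `alt`).
#' @param methWindows `GRanges` with a numeric `level` metadata column
#'   covering the duplicate regions (parental methylation).
#' @param dupRegions `GRanges` of duplicate regions.
#' @param threshold Stratification threshold (default 0.10, strict).
#' @param nSamples Number of samples.
#' @return List with `table` (per-stratum data.frame) and `highFraction`.
#' @export
stratifyByParentalMethylation <- function(mutations, methWindows, dupRegions,
                                          threshold = 0.10, nSamples = 1L) {
  if (length(dupRegions) == 0L || sum(width(reduce(dupRegions))) == 0L)
    stop("no duplicate span to stratify")
  high <- GenomicRanges::intersect(reduce(dupRegions),
                                   reduce(methWindows[!is.na(methWindows$level) &
                                                      methWindows$level > threshold]))
  low <- GenomicRanges::setdiff(reduce(dupRegions), high)
  m <- mutationsInRegions(mutations, dupRegions)
  m <- m[classifyRip(m$ref, m$alt), , drop = FALSE]
  gr <- if (nrow(m)) GRanges(m$chrom, IRanges(m$pos, m$pos)) else GRanges()
  nHigh <- sum(suppressWarnings(overlapsAny(gr, high)))
  nLow <- sum(suppressWarnings(overlapsAny(gr, low)))
  spans <- c(high = sum(width(high)), low = sum(width(low)))
  tab <- data.frame(stratum = c("high", "low"),
                    spanMb = as.numeric(spans) / 1e6,
                    count = c(nHigh, nLow),
                    nSamples = nSamples,
                    rate = c(nHigh, nLow) /
                      pmax(1e-12, as.numeric(spans) / 1e6) / nSamples,
                    stringsAsFactors = FALSE)
  list(table = tab,
       highFraction = if (nHigh + nLow > 0) nHigh / (nHigh + nLow)
                      else NA_real_)
}

#' Count mutations by duplicate-pair distance category
#'
#' Every (mutation, overlapping pair) instance contributes one count to
#' that pair's category, so a mutation in a window that belongs to pairs
#' of different categories is counted once per pair instance. The span of
#' a category is the union of the windows of its pairs.
#'
#' @param mutations Mutation data.frame (`chrom`, `pos`, `ref`, `alt`).
#' @param pairs Pair table ([findDuplicatePairs()]).
#' @param nSamples Number of samples for the rate column.
#' @return data.frame with one row per category: `count`, `spanMb`,
#'   `rate` (per sample per Mb).
#' @export
ratesByDistanceCategory <- function(mutations, pairs, nSamples = 1L) {
  cats <- .DISTANCE_CATEGORIES
  if (nrow(pairs) == 0L)
    return(data.frame(category = character(0), count = integer(0),
                      spanMb = numeric(0), rate = numeric(0),
                      stringsAsFactors = FALSE))
  m <- if (nrow(mutations))
    mutations[classifyRip(mutations$ref, mutations$alt), , drop = FALSE]
  else mutations
  gr <- if (nrow(m)) GRanges(m$chrom, IRanges(m$pos, m$pos)) else GRanges()
  rows <- lapply(cats, function(cat) {
    pc <- pairs[pairs$category == cat, , drop = FALSE]
    if (nrow(pc) == 0L) return(NULL)
    wins <- GRanges(c(pc$chromA, pc$chromB),
                    IRanges(c(pc$startA, pc$startB), c(pc$endA, pc$endB)))
    span <- sum(width(reduce(wins)))
    # one count per (mutation, pair) instance: a mutation hits a pair if
    # it falls in either of the pair's windows
    cnt <- 0L
    if (length(gr)) {
      hitA <- suppressWarnings(findOverlaps(gr, GRanges(pc$chromA,
                                       IRanges(pc$startA, pc$endA))))
      hitB <- suppressWarnings(findOverlaps(gr, GRanges(pc$chromB,
                                       IRanges(pc$startB, pc$endB))))
      inst <- unique(rbind(as.data.frame(hitA), as.data.frame(hitB)))
      cnt <- nrow(inst)
    }
    data.frame(category = cat, count = cnt, spanMb = span / 1e6,
               rate = cnt / (span / 1e6) / nSamples,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-site mutation rate
#'
#' @param nMutations Number of independent mutations observed.
#' @param nSamples Number of progeny individuals assayed.
#' @param regionLength Region length in bp.
#' @return `nMutations / (nSamples * regionLength)`.
#' @export
perSiteRate <- function(nMutations, nSamples, regionLength) {
  if (nMutations < 0) stop("nMutations must be nonnegative")
  if (nSamples <= 0 || regionLength <= 0)
    stop("nSamples and regionLength must be positive")
  nMutations / (nSamples * regionLength)
}

# ---------------------------------------------------------------------------
# Brunner-Munzel

## Core statistic; returns estimate, statistic, df and p. Degenerate
## variance: identical rank profiles give (0.5, p = 1); complete
## separation gives an infinite statistic with p = 0.
bmCore <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  r1 <- r[seq_len(n1)]; r2 <- r[n1 + seq_len(n2)]
  m1 <- mean(r1); m2 <- mean(r2)
  est <- (m2 - (n2 + 1) / 2) / n1
  v1 <- sum((r1 - rank(x) - m1 + (n1 + 1) / 2)^2) / (n1 - 1)
  v2 <- sum((r2 - rank(y) - m2 + (n2 + 1) / 2)^2) / (n2 - 1)
  V <- n1 * v1 + n2 * v2
  if (V == 0) {
    if (m1 == m2)
      return(list(estimate = 0.5, statistic = 0, df = NA_real_, p = 1))
    return(list(estimate = est, statistic = sign(m2 - m1) * Inf,
                df = NA_real_, p = 0))
  }
  stat <- n1 * n2 * (m2 - m1) / (n1 + n2) / sqrt(V)
  df <- V^2 / ((n1 * v1)^2 / (n1 - 1) + (n2 * v2)^2 / (n2 - 1))
  list(estimate = est, statistic = stat, df = df,
       p = 2 * pt(-abs(stat), df))
}

#' Brunner-Munzel test
#'
#' Rank-based two-sample test of the relative effect
#' `P(X < Y) + 0.5 P(X = Y)`, robust to unequal variances. Uses the
#' standard rank-variance estimates with a t approximation on
#' Satterthwaite-type degrees of freedom; the p-value is two-sided.
#' Identical samples (all values tied across both groups) return relative
#' effect 0.5 and p = 1; swapping the samples maps the relative effect
#' `e` to `1 - e` and preserves p.
#'
#' @param x,y Numeric samples with at least 2 observations each.
#' @return List with `estimate` (relative effect), `statistic`, `df`,
#'   `p.value`.
#' @export
brunnerMunzel <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample needs at least 2 observations")
  r <- bmCore(x, y)
  list(estimate = r$estimate, statistic = r$statistic, df = r$df,
       p.value = r$p)
}

#' Exhaustive (or sampled) permutation version of the Brunner-Munzel test
#'
#' Recomputes the Brunner-Munzel statistic under relabelings of the
#' pooled data and returns the two-sided permutation p-value
#' `P(|T*| >= |T|)`; complete-separation permutations count as infinitely
#' extreme. With `maxPermutations = Inf` and small samples the
#' enumeration is exhaustive over all C(n1+n2, n1) splits.
#'
#' @param x,y Numeric samples.
#' @param maxPermutations Cap on enumerated splits; beyond it a seeded
#'   Monte-Carlo sample of splits is used.
#' @param seed Seed for the Monte-Carlo fallback.
#' @return List with `p.value`, `nPermutations`, `exhaustive`.
#' @export
brunnerMunzelPermutation <- function(x, y, maxPermutations = 20000L,
                                     seed = 1L) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample needs at least 2 observations")
  pool <- c(x, y)
  n1 <- length(x); N <- length(pool)
  obs <- abs(bmCore(x, y)$statistic)
  nTot <- choose(N, n1)
  if (nTot <= maxPermutations) {
    idx <- utils::combn(N, n1)
    stats <- apply(idx, 2, function(i) abs(bmCore(pool[i], pool[-i])$statistic))
    exhaustive <- TRUE
  } else {
    set.seed(deriveSeed(seed, "bmperm"))
    stats <- replicate(maxPermutations, {
      i <- sample.int(N, n1)
      abs(bmCore(pool[i], pool[-i])$statistic)
    })
    exhaustive <- FALSE
  }
  list(p.value = mean(stats >= obs - 1e-12),
       nPermutations = length(stats), exhaustive = exhaustive)
}
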