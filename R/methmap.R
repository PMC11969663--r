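# Bisulfite-window methylation analysis: window levels, mutant-vs-WT
# relative change, the change histogram, and HDA-dependence profiles.

#' Window-level methylation from per-cytosine bisulfite counts
#'
#' Sums methylated and unmethylated counts over tiling windows (both
#' strands pooled) and computes the level as
#' `methylated / (methylated + unmethylated)`. Windows without coverage
#' are emitted with level `NA` (the formula is undefined, not zero).
#'
#' @param counts Bisulfite count table (`chrom`, `pos`, `strand`, `meth`,
#'   `unmeth`).
#' @param windowSize Window size in bp.
#' @param chromLengths Optional named lengths; by default windows extend
#'   to the last covered position per chromosome.
#' @return data.frame with `chrom`, `start`, `end` (1-based inclusive),
#'   `meth`, `unmeth`, `coverage`, `level`.
#' @export
windowLevels <- function(counts, windowSize = 100L, chromLengths = NULL) {
  if (windowSize <= 0) stop("windowSize must be positive")
  dt <- data.table::as.data.table(counts)
  lens <- if (is.null(chromLengths)) {
    if (nrow(dt) == 0L) return(data.frame(chrom = character(0),
                                          start = integer(0),
                                          end = integer(0), meth = integer(0),
                                          unmeth = integer(0),
                                          coverage = integer(0),
                                          level = numeric(0)))
    dt[, .(len = max(pos)), by = chrom][, setNames(len, chrom)]
  } else chromLengths
  grid <- data.table::rbindlist(lapply(names(lens), function(ch) {
    n <- ceiling(lens[[ch]] / windowSize)
    data.table::data.table(chrom = ch,
                           start = seq.int(1L, by = windowSize,
                                           length.out = n))
  }))
  grid[, end := pmin(start + as.integer(windowSize) - 1L,
                     as.integer(lens[chrom]))]
  if (nrow(dt)) {
    dt[, start := ((pos - 1L) %/% as.integer(windowSize)) *
                    as.integer(windowSize) + 1L]
    agg <- dt[, .(meth = sum(meth), unmeth = sum(unmeth)), by = .(chrom, start)]
    out <- agg[grid, on = c("chrom", "start")]
  } else out <- grid[, .(chrom, start, meth = NA_integer_,
                         unmeth = NA_integer_)]
  out[is.na(meth), `:=`(meth = 0L, unmeth = 0L)]
  out[, end := grid$end[match(paste(chrom, start), paste(grid$chrom, grid$start))]]
  out[, coverage := meth + unmeth]
  out[, level := data.table::fifelse(coverage > 0, meth / coverage, NA_real_)]
  data.table::setorder(out, chrom, start)
  data.table::setcolorder(out, c("chrom", "start", "end", "meth", "unmeth",
                                 "coverage", "level"))
  as.data.frame(out)
}

#' Relative methylation change of mutant versus wild type per window
#'
#' `change = (mutant - WT) / WT` per window, computed only where the WT
#' level exceeds `minWT` (uninformative near-zero windows are excluded);
#' -1 means complete loss, 0 no change.
#'
#' @param mutant,wt Window tables from [windowLevels()] on identical
#'   grids.
#' @param minWT WT inclusion floor (default 0.1, strict).
#' @return data.frame of included windows with `wtLevel`, `mutantLevel`,
#'   `change`.
#' @export
relativeChange <- function(mutant, wt, minWT = 0.1) {
  if (!identical(wt[, c("chrom", "start", "end")],
                 mutant[, c("chrom", "start", "end")]))
    stop("window grids differ between mutant and wild type")
  keep <- !is.na(wt$level) & wt$level > minWT & !is.na(mutant$level)
  data.frame(chrom = wt$chrom[keep], start = wt$start[keep],
             end = wt$end[keep], wtLevel = wt$level[keep],
             mutantLevel = mutant$level[keep],
             change = (mutant$level[keep] - wt$level[keep]) / wt$level[keep],
             stringsAsFactors = FALSE)
}

#' Histogram of relative methylation changes
#'
#' Bins the relative changes over `[-1, Inf)` with a dedicated first bin
#' for complete loss (change <= -1 + `lossTol`); the counts sum to the
#' number of included windows.
#'
#' @param changes Output of [relativeChange()] (or a numeric vector).
#' @param binWidth Bin width on the relative-change axis (default 0.05).
#' @param lossTol Tolerance below which a change counts as complete loss.
#' @return data.frame with `binLow`, `binHigh`, `count`, `label`.
#' @export
changeHistogram <- function(changes, binWidth = 0.05, lossTol = 0.001) {
  if (binWidth <= 0) stop("binWidth must be positive")
  x <- if (is.data.frame(changes)) changes$change else changes
  loss <- x <= -1 + lossTol
  rest <- x[!loss]
  hi <- if (length(rest)) max(rest, 0) else 0
  breaks <- seq(-1, hi + binWidth, by = binWidth)
  cnt <- if (length(rest))
    table(cut(rest, breaks, right = FALSE, include.lowest = FALSE))
  else table(cut(numeric(0), breaks, right = FALSE))
  out <- data.frame(binLow = breaks[-length(breaks)],
                    binHigh = breaks[-1],
                    count = as.integer(cnt), stringsAsFactors = FALSE)
  out <- rbind(data.frame(binLow = -1, binHigh = -1,
                          count = sum(loss), stringsAsFactors = FALSE), out)
  out$label <- c("complete-loss",
                 sprintf("[%.2f,%.2f)", out$binLow[-1], out$binHigh[-1]))
  out
}

#' Classify an HDA-dependence methylation-loss profile
#'
#' Operationalises the contrast between localised complete loss (a small
#' fraction of fully dependent windows, the rest unchanged) and a uniform
#' modest genome-wide reduction: reports (a) the fraction of windows with
#' change <= `dependentThreshold`, (b) the median change of the remaining
#' windows, and (c) a categorical label: `localized-loss` if (a) >
#' `dependentFractionMin` and (b) > `medianFloor`; `global-shift` if (a)
#' <= `dependentFractionMin` and (b) < `medianFloor`; `no-change`
#' otherwise.
#'
#' @param changes Output of [relativeChange()] (or a numeric vector) with
#'   at least `minWindows` included windows.
#' @param dependentThreshold Change at or below which a window counts as
#'   fully dependent (default -0.9).
#' @param dependentFractionMin Fraction cut between localised and global
#'   profiles (default 0.05).
#' @param medianFloor Median-change cut (default -0.1).
#' @param minWindows Minimum number of included windows (default 20).
#' @return List with `dependentFraction`, `medianOther`, `profile`.
#' @export
classifyLossProfile <- function(changes, dependentThreshold = -0.9,
                                dependentFractionMin = 0.05,
                                medianFloor = -0.1, minWindows = 20L) {
  x <- if (is.data.frame(changes)) changes$change else changes
  if (length(x) < minWindows)
    stop("need at least ", minWindows, " included windows")
  dep <- x <= dependentThreshold
  frac <- mean(dep)
  medOther <- if (any(!dep)) stats::median(x[!dep]) else NA_real_
  profile <- if (frac > dependentFractionMin &&
                 !is.na(medOther) && medOther > medianFloor) "localized-loss"
  else if (frac <= dependentFractionMin &&
           !is.na(medOther) && medOther < medianFloor) "global-shift"
  else "no-change"
  list(dependentFraction = frac, medianOther = medOther, profile = profile)
}
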