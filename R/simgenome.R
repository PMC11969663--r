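# Forward simulator of RIP and heterochromatin dynamics in haploid crosses.
#
# The model: duplicated sequence is recognised per spore with probability
# pEvent (pEventLinked for linked R-L-R testers). Given recognition, each
# carried copy receives a count of clustered G:C->A:T mutations drawn with
# mean intensity(class, genotype) * span_kb, where the intensity of a
# chromatin class decomposes into a RID-only, a DIM-2-only and a
# synergistic coefficient. Chromatin of newly mutated duplicates advances
# through euchromatic -> transitional -> constitutive states; HDA-1 gates
# the establishment step, DIM-2 gates every emitted methylation level.

# ---------------------------------------------------------------------------
# Default parameterisation

#' Default chromatin state-machine parameters
#'
#' Target methylation means of the heterochromatin state machine:
#' * `transitionalTarget`: level of newly established (first-generation)
#'   heterochromatin on a RIPed young duplicate (0.33).
#' * `intactTargets`: maintained level of the young duplicate in an intact
#'   lineage at generations 1..4 (0.330 .. 0.323).
#' * `koTargets`: level after a vegetative hda-1 knockout applied at
#'   generations 1..4 (0.004, 0.163, 0.140, 0.225) -- the influence of
#'   HDA-1 fades as heterochromatin matures.
#' * `silencedTargets`: residual level of a lineage crossed in an
#'   hda-1-null background, generations 1..4 (establishment blocked).
#' * `hda1DependentFraction`: fraction of established constitutive windows
#'   whose methylation collapses on hda-1 knockout (0.135).
#' * `hda23Factor`: uniform multiplicative reduction of constitutive
#'   methylation under hda-2 or hda-3 knockout (0.75).
#' * `hda2EstablishTarget`, `hda3EstablishTarget`: reduced establishment
#'   targets when hda-2 / hda-3 are absent at establishment.
#' * `silencedCeiling`: hard ceiling on hda-1-null lineage methylation.
#'
#' @return Named list of parameters.
#' @export
defaultChromatinParams <- function() {
  list(transitionalTarget   = 0.33,
       intactTargets        = c(0.330, 0.328, 0.325, 0.323),
       koTargets            = c(0.004, 0.163, 0.140, 0.225),
       silencedTargets      = c(0.004, 0.006, 0.009, 0.011),
       hda1DependentFraction = 0.135,
       hda23Factor          = 0.75,
       hda2EstablishTarget  = 0.14,
       hda3EstablishTarget  = 0.10,
       silencedCeiling      = 0.02)
}

## Intensity calibration constants (see the methods vignette):
## - euchromatic young duplicates: conditional total 422.4 mutations per
##   11 kb copy per recognised spore (so the unconditional mean at
##   pEvent = 0.5 is 211.2); split 50% RID-only, 0.8% DIM-2-only,
##   49.2% synergistic, so single knockouts leave 50% (dim-2 null) and
##   0.8% (rid null) of the wild-type rate.
## - genomic heterochromatic duplicates: 65 mutations per spore summed
##   over the default planted heterochromatic span, split 18.2% RID-only,
##   32.1% DIM-2-only, 49.7% synergistic (single knockouts leave 32.1% /
##   18.2%); the high- vs low-methylation class ratio 4.308 places ~89.6%
##   of heterochromatic RIP in the high-methylation stratum.
## - linker: entirely synergistic, so either single knockout silences it.
.EU_TOTAL_PER_KB <- 422.4 / 11
.HET_GENOME_TOTAL <- 65
.HET_CLASS_RATIO <- 4.308
.LINKER_PER_KB <- 20

#' Default RIP intensity model
#'
#' Coefficients are expressed as expected mutations per recognised spore
#' per kb of duplicate. The `constitutive` and `transitional` rows are
#' calibrated jointly with [defaultSimConfig()]'s planted spans so that a
#' wild-type cross carries about 65 heterochromatic-duplicate mutations
#' per spore, of which a rid-null cross retains 32.1% and a dim-2-null
#' cross 18.2%.
#'
#' @param hetHighSpanKb,hetLowSpanKb Planted span (kb) of high- and
#'   low-methylation heterochromatic duplicates used for calibration.
#' @param pEvent Per-spore recognition probability used for calibration.
#' @return An [IntensityModel-class].
#' @export
defaultIntensityModel <- function(hetHighSpanKb = 48, hetLowSpanKb = 24,
                                  pEvent = 0.5) {
  rHigh <- .HET_GENOME_TOTAL / pEvent /
    (hetHighSpanKb + hetLowSpanKb / .HET_CLASS_RATIO)
  rLow <- rHigh / .HET_CLASS_RATIO
  eu <- .EU_TOTAL_PER_KB
  m <- rbind(
    euchromatic  = eu    * c(0.500, 0.008, 0.492),
    transitional = rLow  * c(0.182, 0.321, 0.497),
    constitutive = rHigh * c(0.182, 0.321, 0.497),
    linker       = .LINKER_PER_KB * c(0, 0, 1))
  colnames(m) <- c("rid", "dim2", "syn")
  intensityModel(m)
}

#' Default simulation configuration
#'
#' Two 150 kb chromosomes carrying:
#' * `Sly1`: an unlinked 11 kb transposon pair at 97.4% identity on
#'   different chromosomes, copy A in parent 1 only and copy B in parent 2
#'   only, euchromatic and unmethylated (a naturally young duplicate);
#' * `RLR`: an 802 bp repeat / 729 bp linker / 802 bp repeat tester with
#'   AT fraction 45.64%, carried by parent 1;
#' * `hetA`..`hetD`: four dispersed 6 kb duplicate pairs shared by both
#'   parents, constitutive heterochromatin with parental methylation
#'   0.35-0.50 (the historically methylated stratum, 48 kb);
#' * `hetE`..`hetF`: two dispersed 6 kb pairs with parental methylation
#'   0.05 (the low-methylation stratum, 24 kb).
#'
#' @param seed Default master seed stored in the configuration.
#' @param ... Overrides for `pEvent`, `pEventLinked`, `depth`, `errorRate`,
#'   `baseAT`, `overdispersion`, `clusterParams`, `chromatin`.
#' @return A [RipSimConfig-class].
#' @export
defaultSimConfig <- function(seed = 1L, ...) {
  hetHigh <- list(fam = c("hetA", "hetB", "hetC", "hetD"),
                  meth = c(0.45, 0.40, 0.50, 0.42),
                  startA = c(70001L, 90001L, 110001L, 130001L))
  specs <- c(
    list(duplicateSpec("Sly1", "transposon-pair",
                       chrom = c("chrI", "chrII"), start = c(20001L, 20001L),
                       copyLength = 11000L, identity = 0.974,
                       presence = c("p1", "p2"), class = "euchromatic",
                       parentMeth = 0),
         duplicateSpec("RLR", "R-L-R", chrom = "chrI", start = 50001L,
                       copyLength = 802L, linkerLength = 729L, identity = 1,
                       atFraction = 0.4564, presence = "p1",
                       class = "euchromatic", parentMeth = 0)),
    lapply(seq_along(hetHigh$fam), function(i)
      duplicateSpec(hetHigh$fam[i], "dispersed-pair",
                    chrom = c("chrI", "chrII"),
                    start = rep(hetHigh$startA[i], 2L),
                    copyLength = 6000L, identity = 0.85,
                    presence = "both", class = "constitutive",
                    parentMeth = hetHigh$meth[i])),
    list(duplicateSpec("hetE", "dispersed-pair",
                       chrom = c("chrI", "chrII"), start = c(40001L, 40001L),
                       copyLength = 6000L, identity = 0.85,
                       presence = "both", class = "transitional",
                       parentMeth = 0.05),
         duplicateSpec("hetF", "dispersed-pair",
                       chrom = c("chrI", "chrII"), start = c(58001L, 58001L),
                       copyLength = 6000L, identity = 0.85,
                       presence = "both", class = "transitional",
                       parentMeth = 0.05)))
  defaults <- list(pEvent = 0.5, pEventLinked = 0.9, depth = 40,
                   errorRate = 0.002, baseAT = 0.5, overdispersion = Inf,
                   clusterParams = list(centersPerMutation = 1 / 15,
                                        offsetMean = 150),
                   chromatin = defaultChromatinParams())
  ov <- list(...)
  bad <- setdiff(names(ov), names(defaults))
  if (length(bad)) stop("unknown configuration field(s): ",
                        paste(bad, collapse = ", "))
  defaults[names(ov)] <- ov
  new("RipSimConfig",
      chromLengths = c(chrI = 150000L, chrII = 150000L),
      dupSpecs = specs,
      intensity = defaultIntensityModel(pEvent = defaults$pEvent),
      chromatin = defaults$chromatin,
      pEvent = defaults$pEvent, pEventLinked = defaults$pEventLinked,
      depth = defaults$depth, errorRate = defaults$errorRate,
      baseAT = defaults$baseAT, overdispersion = defaults$overdispersion,
      clusterParams = defaults$clusterParams, seed = as.integer(seed))
}

#' General simulation configuration constructor
#'
#' Like [defaultSimConfig()] but with explicit chromosome lengths and
#' duplicate specifications, for custom simulation designs.
#'
#' @param chromLengths Named vector of chromosome lengths (bp).
#' @param dupSpecs List of [DuplicateSpec-class] objects (may be empty).
#' @param intensity An [IntensityModel-class]; default
#'   [defaultIntensityModel()].
#' @param seed Master seed.
#' @inheritParams defaultSimConfig
#' @return A [RipSimConfig-class].
#' @export
simConfig <- function(chromLengths, dupSpecs = list(),
                      intensity = defaultIntensityModel(), seed = 1L, ...) {
  base <- defaultSimConfig(seed = seed, ...)
  new("RipSimConfig",
      chromLengths = setNames(as.integer(chromLengths), names(chromLengths)),
      dupSpecs = dupSpecs, intensity = intensity, chromatin = base@chromatin,
      pEvent = base@pEvent, pEventLinked = base@pEventLinked,
      depth = base@depth, errorRate = base@errorRate, baseAT = base@baseAT,
      overdispersion = base@overdispersion,
      clusterParams = base@clusterParams, seed = as.integer(seed))
}

# ---------------------------------------------------------------------------
# Intensity

#' Expected RIP intensity for a chromatin class and genotype
#'
#' Returns `c_RID * I(rid) + c_DIM2 * I(dim2) + c_SYN * I(rid) * I(dim2)`
#' for the class, in mutations per recognised spore per kb. A rid/dim-2
#' double deletion therefore always yields 0.
#'
#' @param class Chromatin class name (a row of the model).
#' @param genotype Character vector of deleted genes (see
#'   [normalizeGenotype()]).
#' @param model An [IntensityModel-class].
#' @return Numeric rate (mutations / recognised spore / kb).
#' @export
expectedRipIntensity <- function(class, genotype = character(),
                                 model = defaultIntensityModel()) {
  if (!class %in% chromatinClasses(model))
    stop("unknown chromatin class: ", class)
  genotype <- normalizeGenotype(genotype)
  co <- intensityCoefficients(model)[class, ]
  rid <- genePresent("rid", genotype)
  dim2 <- genePresent("dim-2", genotype)
  unname(co["rid"] * rid + co["dim2"] * dim2 + co["syn"] * rid * dim2)
}

# ---------------------------------------------------------------------------
# Parental genome construction

## Expand a DuplicateSpec into per-copy 1-based [start, end] placements.
expandSpec <- function(spec) {
  pl <- spec@placements
  if (spec@kind == "R-L-R") {
    L <- spec@copyLength; lk <- spec@linkerLength
    s <- pl$start[1]
    data.frame(family = spec@family, kind = spec@kind,
               copy = c("R1", "L", "R2"),
               chrom = pl$chrom[1],
               start = c(s, s + L, s + L + lk),
               end = c(s + L - 1L, s + L + lk - 1L, s + 2L * L + lk - 1L),
               presence = pl$presence[1],
               class = c(pl$class[1], "linker", pl$class[1]),
               parentMeth = pl$parentMeth[1],
               stringsAsFactors = FALSE)
  } else {
    data.frame(family = spec@family, kind = spec@kind, copy = pl$copy,
               chrom = pl$chrom, start = pl$start,
               end = pl$start + spec@copyLength - 1L,
               presence = pl$presence, class = pl$class,
               parentMeth = pl$parentMeth, stringsAsFactors = FALSE)
  }
}

#' Build a pair of haploid parental genomes with planted duplicates
#'
#' Generates a shared random genomic background, then plants every
#' duplicate family of the configuration: both copies of a dispersed pair
#' into both parents, copy A of a transposon pair into parent 1 only and
#' copy B into parent 2 only (the locus holds unrelated background
#' sequence in the non-carrying parent), and the R-L-R cassette into its
#' carrying parent(s). The second copy of each family is derived from the
#' first by random substitutions realising the identity target.
#'
#' @param config A [RipSimConfig-class].
#' @param seed Master seed (defaults to the configuration's seed).
#' @return A [ParentalPair-class].
#' @export
buildParentalGenomes <- function(config, seed = config@seed) {
  validObject(config)
  set.seed(deriveSeed(seed, "parents"))
  copies <- do.call(rbind, lapply(config@dupSpecs, expandSpec))
  if (!is.null(copies)) {
    if (!all(copies$chrom %in% names(config@chromLengths)))
      stop("placement on unknown chromosome")
    if (any(copies$end > config@chromLengths[copies$chrom]))
      stop("placement extends beyond its chromosome")
    gr <- GRanges(copies$chrom, IRanges(copies$start, copies$end))
    if (length(gr) > 1 && any(GenomicRanges::countOverlaps(gr, gr) > 1L))
      stop("overlapping duplicate placements")
  }
  genome1 <- lapply(config@chromLengths, randomSequence, at = config@baseAT)
  genome2 <- genome1
  if (!is.null(copies)) {
    for (spec in config@dupSpecs) {
      at <- if (is.na(spec@atFraction)) config@baseAT else spec@atFraction
      k <- round((1 - spec@identity) * spec@copyLength)
      if (spec@identity < 1 && k == 0L)
        stop(sprintf("identity target %.4f unreachable at copy length %d",
                     spec@identity, spec@copyLength))
      seqA <- randomSequenceExactAT(spec@copyLength, at)
      seqB <- if (spec@identity == 1) seqA else mutateToIdentity(seqA, spec@identity)
      parts <- expandSpec(spec)
      seqs <- if (spec@kind == "R-L-R") {
        c(R1 = seqA, L = randomSequenceExactAT(spec@linkerLength, at), R2 = seqB)
      } else c(A = seqA, B = seqB)
      for (i in seq_len(nrow(parts))) {
        s <- seqs[[parts$copy[i]]]
        tgt <- switch(parts$presence[i], both = c(1L, 2L), p1 = 1L, p2 = 2L,
                      stop("presence must be both, p1 or p2"))
        for (w in tgt) {
          g <- if (w == 1L) genome1 else genome2
          substr(g[[parts$chrom[i]]], parts$start[i], parts$end[i]) <- s
          if (w == 1L) genome1 <- g else genome2 <- g
        }
      }
    }
  }
  ann <- if (is.null(copies)) GRanges() else {
    g <- GRanges(copies$chrom, IRanges(copies$start, copies$end))
    mcols(g) <- DataFrame(copies[, c("family", "kind", "copy", "class",
                                     "presence", "parentMeth")])
    g
  }
  new("ParentalPair",
      genome1 = DNAStringSet(unlist(genome1)),
      genome2 = DNAStringSet(unlist(genome2)),
      duplicates = ann, config = config)
}

# ---------------------------------------------------------------------------
# Clustered mutation placement

#' Place clustered G:C -> A:T mutations in a sequence
#'
#' Draws `1 + Poisson(n * centersPerMutation)` cluster centres among the
#' G/C sites of the region, assigns the `n` mutations to centres
#' multinomially, offsets each by a signed geometric displacement (mean
#' `offsetMean` bp) and snaps to the nearest unused G/C site. Every
#' returned substitution is C->T or G->A.
#'
#' @param seq Region sequence (character scalar).
#' @param n Number of mutations to place.
#' @param clusterParams List with `centersPerMutation` and `offsetMean`.
#' @param seed Optional seed.
#' @param gcPos Optional precomputed integer vector of G/C positions.
#' @return data.frame with columns `pos` (1-based), `ref`, `alt`.
#' @export
placeClusteredMutations <- function(seq, n,
                                    clusterParams = list(centersPerMutation = 1 / 15,
                                                         offsetMean = 150),
                                    seed = NULL, gcPos = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n < 0) stop("n must be nonnegative")
  if (is.null(gcPos)) {
    v <- strsplit(seq, "")[[1]]
    gcPos <- which(v == "G" | v == "C")
    bases <- v
  } else bases <- NULL
  empty <- data.frame(pos = integer(0), ref = character(0), alt = character(0))
  if (n == 0L) return(empty)
  if (length(gcPos) < n)
    stop(sprintf("region has %d G:C sites but %d mutations requested (short by %d)",
                 length(gcPos), n, n - length(gcPos)))
  k <- 1L + rpois(1L, n * clusterParams$centersPerMutation)
  centers <- sample(gcPos, min(k, length(gcPos)))
  assigned <- centers[sample.int(length(centers), n, replace = TRUE)]
  off <- rgeom(n, 1 / (clusterParams$offsetMean + 1)) *
    sample(c(-1L, 1L), n, replace = TRUE)
  target <- assigned + off
  # snap each target to the nearest still-unused G/C site
  used <- logical(length(gcPos))
  pos <- integer(n)
  for (i in seq_len(n)) {
    j <- findInterval(target[i], gcPos)
    j <- max(1L, min(length(gcPos), j))
    if (j < length(gcPos) &&
        abs(gcPos[j + 1L] - target[i]) < abs(gcPos[j] - target[i])) j <- j + 1L
    lo <- j; hi <- j
    while (used[j]) {
      lo <- lo - 1L; hi <- hi + 1L
      if (lo >= 1L && !used[lo]) { j <- lo; break }
      if (hi <= length(gcPos) && !used[hi]) { j <- hi; break }
      if (lo < 1L && hi > length(gcPos)) stop("no free G:C site left")
    }
    used[j] <- TRUE
    pos[i] <- gcPos[j]
  }
  pos <- sort(pos)
  ref <- if (is.null(bases)) substring(seq, pos, pos) else bases[pos]
  data.frame(pos = pos, ref = ref,
             alt = ifelse(ref == "C", "T", "A"),
             stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# Chromatin state machine

#' Advance the chromatin state of a duplicate copy through one cross
#'
#' Transition rules: a euchromatic copy that is RIPed (with RID present)
#' establishes transitional heterochromatin at target 0.33 when HDA-1 is
#' present, a near-zero silenced-null state when HDA-1 is absent, or a
#' reduced transitional state (0.14 / 0.10) when hda-2 / hda-3 are absent
#' at establishment. A transitional copy matures to constitutive
#' heterochromatin at the next cross; constitutive and silenced-null
#' states persist. Absence of dim-2 zeroes emitted methylation but does
#' not change the underlying state.
#'
#' @param state Current state (`"euchromatic"`, `"transitional"`,
#'   `"constitutive"`, `"silenced-null"`).
#' @param genotype Character vector of deleted genes.
#' @param generation Generation index (1-based).
#' @param ripEvent Logical: was the copy recognised by RIP in this cross?
#' @param params Chromatin parameters ([defaultChromatinParams()]).
#' @param level Current methylation level of the copy (used as the
#'   maintained target for constitutive copies; `NA` uses the generation
#'   default).
#' @return List with elements `state` and `target` (methylation mean).
#' @export
evolveChromatin <- function(state, genotype = character(), generation = 1L,
                            ripEvent = FALSE,
                            params = defaultChromatinParams(), level = NA) {
  if (!state %in% .CHROMATIN_STATES)
    stop("unknown chromatin state: ", state)
  genotype <- normalizeGenotype(genotype)
  g <- min(max(1L, as.integer(generation)), 4L)
  if (state == "euchromatic") {
    if (ripEvent && genePresent("rid", genotype)) {
      if (!genePresent("hda-1", genotype))
        return(list(state = "silenced-null",
                    target = min(params$silencedTargets[g],
                                 params$silencedCeiling)))
      if (!genePresent("hda-2", genotype))
        return(list(state = "transitional",
                    target = params$hda2EstablishTarget))
      if (!genePresent("hda-3", genotype))
        return(list(state = "transitional",
                    target = params$hda3EstablishTarget))
      return(list(state = "transitional", target = params$transitionalTarget))
    }
    return(list(state = "euchromatic", target = 0))
  }
  if (state == "transitional")
    return(list(state = "constitutive", target = params$intactTargets[g]))
  if (state == "constitutive")
    return(list(state = "constitutive",
                target = if (is.na(level)) params$intactTargets[g] else level))
  list(state = "silenced-null",
       target = min(params$silencedTargets[g], params$silencedCeiling))
}

#' Methylation target after a vegetative knockout of an existing state
#'
#' Models knocking a gene out of an already-established strain (no
#' further cross): hda-1 reduces a transitional/constitutive copy to the
#' generation-dependent knockout target (0.004, 0.163, 0.140, 0.225 for
#' generations 1..4); hda-2/hda-3 apply a uniform multiplicative
#' reduction; dim-2 eliminates methylation entirely.
#'
#' @inheritParams evolveChromatin
#' @param knockout Character vector of genes knocked out vegetatively.
#' @return Target methylation mean after the knockout.
#' @export
knockoutChromatin <- function(state, generation, knockout,
                              params = defaultChromatinParams(), level = NA) {
  if (!state %in% .CHROMATIN_STATES)
    stop("unknown chromatin state: ", state)
  knockout <- normalizeGenotype(knockout)
  g <- min(max(1L, as.integer(generation)), 4L)
  base <- if (!is.na(level)) level
          else switch(state,
                      euchromatic = 0,
                      transitional = if (g == 1L) params$transitionalTarget
                                     else params$intactTargets[g],
                      constitutive = params$intactTargets[g],
                      `silenced-null` = params$silencedTargets[g])
  if (!genePresent("dim-2", knockout)) return(0)
  if (!genePresent("hda-1", knockout) &&
      state %in% c("transitional", "constitutive"))
    return(params$koTargets[g])
  if ((!genePresent("hda-2", knockout) || !genePresent("hda-3", knockout)) &&
      state %in% c("transitional", "constitutive"))
    return(base * params$hda23Factor)
  base
}

# ---------------------------------------------------------------------------
# Cross simulation

## Copy table with cached sequences and G/C positions for a ParentalPair.
copyTable <- function(parents) {
  ann <- duplicateAnnotation(parents)
  if (length(ann) == 0L) return(NULL)
  df <- as.data.frame(ann)
  df$chrom <- as.character(df$seqnames)
  g1 <- asChromList(parents@genome1)
  g2 <- asChromList(parents@genome2)
  df$seq <- vapply(seq_len(nrow(df)), function(i) {
    g <- if (df$presence[i] == "p2") g2 else g1
    substring(g[[df$chrom[i]]], df$start[i], df$end[i])
  }, character(1))
  df$gcPos <- lapply(df$seq, function(s) {
    v <- strsplit(s, "")[[1]]; which(v == "G" | v == "C")
  })
  df
}

#' Simulate one sexual cross between the two parents
#'
#' Spores come in tetrads of four; each chromosome segregates 2:2 within a
#' tetrad. Each duplicate family is recognised by RIP per spore with
#' probability `pEvent` (`pEventLinked` for R-L-R testers); given
#' recognition, each copy the spore carries receives a Poisson (or
#' negative-binomial) number of clustered G:C->A:T mutations with mean
#' `intensity(class, genotype) * span_kb`, and its chromatin advances via
#' [evolveChromatin()].
#'
#' @param parents A [ParentalPair-class].
#' @param genotype Deleted genes of the crossing background.
#' @param nTetrads Number of tetrads (4 spores each).
#' @param seed Master seed.
#' @param generation Generation index forwarded to the state machine.
#' @return A [RipCross-class].
#' @export
simulateCross <- function(parents, genotype = character(), nTetrads = 50L,
                          seed = parents@config@seed, generation = 1L) {
  if (nTetrads < 0) stop("nTetrads must be nonnegative")
  genotype <- normalizeGenotype(genotype)
  config <- parents@config
  set.seed(deriveSeed(seed, "cross", generation))
  copies <- copyTable(parents)
  chroms <- names(config@chromLengths)
  model <- config@intensity
  fams <- if (is.null(copies)) character(0) else unique(copies$family)
  famKind <- if (length(fams))
    vapply(fams, function(f) copies$kind[match(f, copies$family)], character(1))
  else character(0)
  spores <- vector("list", 4L * nTetrads)
  truth <- vector("list", 4L * nTetrads)
  sporeIdx <- 0L
  for (t in seq_len(nTetrads)) {
    origins <- vapply(chroms, function(ch) sample(rep(c("p1", "p2"), 2L)),
                      character(4))
    if (length(chroms) == 1L) origins <- matrix(origins, ncol = 1L,
                                                dimnames = list(NULL, chroms))
    for (s in 1:4) {
      sporeIdx <- sporeIdx + 1L
      origin <- origins[s, ]
      events <- setNames(logical(length(fams)), fams)
      mutList <- list()
      methRows <- list()
      for (fi in seq_along(fams)) {
        f <- fams[fi]
        p <- if (famKind[fi] == "R-L-R") config@pEventLinked else config@pEvent
        ev <- runif(1) < p
        events[f] <- ev
        rows <- which(copies$family == f)
        for (r in rows) {
          carried <- copies$presence[r] == "both" ||
            copies$presence[r] == origin[[copies$chrom[r]]]
          if (!carried) next
          cls <- copies$class[r]
          if (ev) {
            rate <- expectedRipIntensity(cls, genotype, model)
            lambda <- rate * (copies$end[r] - copies$start[r] + 1L) / 1000
            nm <- if (is.finite(config@overdispersion))
              rnbinom(1L, size = config@overdispersion, mu = lambda)
            else rpois(1L, lambda)
            nm <- min(nm, length(copies$gcPos[[r]]))
            if (nm > 0L) {
              mu <- placeClusteredMutations(copies$seq[r], nm,
                                            config@clusterParams,
                                            gcPos = copies$gcPos[[r]])
              mutList[[length(mutList) + 1L]] <- data.frame(
                spore = sporeIdx, chrom = copies$chrom[r],
                pos = copies$start[r] - 1L + mu$pos,
                ref = mu$ref, alt = mu$alt, family = f,
                copy = copies$copy[r], class = cls,
                stringsAsFactors = FALSE)
            }
          }
          chromState <- if (cls %in% c("euchromatic", "linker")) "euchromatic"
                        else cls
          evres <- evolveChromatin(chromState, genotype, generation, ev,
                                   config@chromatin,
                                   level = copies$parentMeth[r])
          methRows[[length(methRows) + 1L]] <- data.frame(
            family = f, copy = copies$copy[r], chrom = copies$chrom[r],
            start = copies$start[r], end = copies$end[r],
            state = evres$state, target = evres$target,
            stringsAsFactors = FALSE)
        }
      }
      spores[[sporeIdx]] <- list(
        id = sporeIdx, tetrad = t, origin = origin, events = events,
        meth = if (length(methRows)) do.call(rbind, methRows)
               else data.frame())
      truth[[sporeIdx]] <- if (length(mutList)) do.call(rbind, mutList)
                           else NULL
    }
  }
  truthDf <- if (length(truth) && any(!vapply(truth, is.null, logical(1))))
    do.call(rbind, truth[!vapply(truth, is.null, logical(1))])
  else data.frame(spore = integer(0), chrom = character(0), pos = integer(0),
                  ref = character(0), alt = character(0),
                  family = character(0), copy = character(0),
                  class = character(0), stringsAsFactors = FALSE)
  rownames(truthDf) <- NULL
  new("RipCross", spores = spores, truth = truthDf, parents = parents,
      genotype = genotype, generation = as.integer(generation))
}

#' Materialise the genome sequence of one spore
#'
#' Takes each chromosome from the spore's parent of origin and applies the
#' spore's true mutations, so that a direct sequence diff against the
#' parent of origin recovers exactly the truth table.
#'
#' @param cross A [RipCross-class].
#' @param spore Spore index.
#' @return A `DNAStringSet`.
#' @export
sporeGenome <- function(cross, spore) {
  sp <- cross@spores[[spore]]
  g1 <- asChromList(cross@parents@genome1)
  g2 <- asChromList(cross@parents@genome2)
  out <- g1
  for (ch in names(out))
    out[[ch]] <- if (sp$origin[[ch]] == "p1") g1[[ch]] else g2[[ch]]
  tr <- cross@truth[cross@truth$spore == spore, , drop = FALSE]
  if (nrow(tr)) for (ch in unique(tr$chrom)) {
    sub <- tr[tr$chrom == ch, ]
    v <- strsplit(out[[ch]], "")[[1]]
    stopifnot(all(v[sub$pos] == sub$ref))
    v[sub$pos] <- sub$alt
    out[[ch]] <- paste(v, collapse = "")
  }
  DNAStringSet(unlist(out))
}

## Carrier status of each spore for a given family copy.
carriesCopy <- function(cross, family, copy) {
  ann <- as.data.frame(duplicateAnnotation(cross@parents))
  row <- ann[ann$family == family & ann$copy == copy, ]
  if (nrow(row) != 1L) stop("no such family/copy: ", family, "/", copy)
  vapply(cross@spores, function(sp) {
    row$presence == "both" ||
      row$presence == sp$origin[[as.character(row$seqnames)]]
  }, logical(1))
}

#' Fraction of copy-carrying spores with at least one RIP mutation
#'
#' @param cross A [RipCross-class].
#' @param family Duplicate family name.
#' @param copy Copy label (default `"A"`).
#' @return List with `fraction`, `nCarriers`, `nRipped`.
#' @export
ripFrequency <- function(cross, family = "Sly1", copy = "A") {
  carriers <- which(carriesCopy(cross, family, copy))
  tr <- cross@truth
  ripped <- vapply(carriers, function(i)
    any(tr$spore == i & tr$family == family & tr$copy == copy), logical(1))
  list(fraction = if (length(carriers)) mean(ripped) else NA_real_,
       nCarriers = length(carriers), nRipped = sum(ripped))
}

#' Mean mutation count per spore in a set of duplicate copies
#'
#' @param cross A [RipCross-class].
#' @param families Families to count (default all).
#' @param copies Copy labels to count (default all).
#' @param perCarrier If TRUE (default for single-copy queries), average
#'   over spores carrying the copy; otherwise over all spores.
#' @return Mean count per (carrier) spore.
#' @export
mutationsPerSpore <- function(cross, families = NULL, copies = NULL,
                              perCarrier = FALSE) {
  tr <- cross@truth
  keep <- rep(TRUE, nrow(tr))
  if (!is.null(families)) keep <- keep & tr$family %in% families
  if (!is.null(copies)) keep <- keep & tr$copy %in% copies
  tr <- tr[keep, , drop = FALSE]
  if (perCarrier) {
    stopifnot(length(families) == 1L, length(copies) == 1L)
    carriers <- which(carriesCopy(cross, families, copies))
    if (!length(carriers)) return(NA_real_)
    counts <- vapply(carriers, function(i) sum(tr$spore == i), numeric(1))
    return(mean(counts))
  }
  nrow(tr) / length(cross@spores)
}

# ---------------------------------------------------------------------------
# Multi-generation lineage

#' Follow a young duplicate through repeated crosses
#'
#' Emulates the progressive heterochromatin-formation design: progeny
#' carrying the followed copy are repeatedly crossed to a naive partner.
#' At each generation the copy is recognised by RIP if any of
#' `candidateSpores` independent spores is recognised (progeny carrying
#' RIP are selected for the next cross), mutations accumulate in the copy
#' sequence (raising its AT fraction), and the chromatin state advances.
#'
#' @param parents A [ParentalPair-class].
#' @param nGenerations Number of successive crosses.
#' @param genotype Deleted genes of the crossing background (applies to
#'   every generation, e.g. `"hda-1"` for an establishment-blocked
#'   lineage).
#' @param family,copy Followed duplicate copy.
#' @param seed Master seed.
#' @param candidateSpores Number of spores screened per generation when
#'   selecting a RIPed carrier.
#' @return A [RipLineage-class].
#' @export
simulateLineage <- function(parents, nGenerations = 4L,
                            genotype = character(), family = "Sly1",
                            copy = "A", seed = parents@config@seed,
                            candidateSpores = 16L) {
  genotype <- normalizeGenotype(genotype)
  config <- parents@config
  set.seed(deriveSeed(seed, "lineage", paste(genotype, collapse = ";")))
  ann <- as.data.frame(duplicateAnnotation(parents))
  row <- ann[ann$family == family & ann$copy == copy, ]
  if (nrow(row) != 1L) stop("no such family/copy: ", family, "/", copy)
  g <- asChromList(if (row$presence == "p2") parents@genome2 else parents@genome1)
  seq <- substring(g[[as.character(row$seqnames)]], row$start, row$end)
  state <- "euchromatic"
  level <- row$parentMeth
  p <- if (row$kind == "R-L-R") config@pEventLinked else config@pEvent
  rows <- vector("list", nGenerations)
  for (gen in seq_len(nGenerations)) {
    ev <- any(runif(candidateSpores) < p)
    newMut <- 0L
    if (ev) {
      cls <- switch(state, euchromatic = "euchromatic",
                    `silenced-null` = "euchromatic", "constitutive")
      rate <- expectedRipIntensity(cls, genotype, config@intensity)
      lambda <- rate * nchar(seq) / 1000
      nm <- rpois(1L, lambda)
      v <- strsplit(seq, "")[[1]]
      gc <- which(v == "G" | v == "C")
      nm <- min(nm, length(gc))
      if (nm > 0L) {
        mu <- placeClusteredMutations(seq, nm, config@clusterParams, gcPos = gc)
        v[mu$pos] <- mu$alt
        seq <- paste(v, collapse = "")
        newMut <- nm
      }
    }
    st <- evolveChromatin(state, genotype, gen, ev, config@chromatin,
                          level = if (state == "constitutive") NA else level)
    state <- st$state
    level <- st$target
    rows[[gen]] <- data.frame(generation = gen, state = state,
                              target = st$target,
                              atFraction = atFraction(seq),
                              newMutations = newMut)
  }
  new("RipLineage", trajectory = do.call(rbind, rows), sequence = seq,
      genotype = genotype, family = family)
}

#' Measure bisulfite methylation of a lineage's followed copy
#'
#' Emits per-cytosine binomial bisulfite counts at the lineage's final
#' methylation target (optionally after a vegetative knockout via
#' [knockoutChromatin()]) and returns the pooled level.
#'
#' @param lineage A [RipLineage-class].
#' @param knockout Genes knocked out vegetatively before measuring
#'   (e.g. `"hda-1"`), or `NULL`.
#' @param depth Mean read depth per cytosine.
#' @param seed Seed for the binomial draws.
#' @return List with `level` (pooled methylated fraction), `target`,
#'   `nCytosines`.
#' @export
measureLineageMethylation <- function(lineage, knockout = NULL, depth = 40,
                                      seed = 1L) {
  set.seed(deriveSeed(seed, "lineagebs"))
  tr <- lineage@trajectory
  gen <- max(tr$generation)
  state <- tr$state[nrow(tr)]
  target <- tr$target[nrow(tr)]
  if (!is.null(knockout))
    target <- knockoutChromatin(state, gen, knockout, level = target)
  v <- strsplit(lineage@sequence, "")[[1]]
  nC <- sum(v == "C" | v == "G")   # cytosines on either strand
  cov <- rpois(nC, depth)
  meth <- rbinom(nC, cov, target)
  list(level = sum(meth) / max(1, sum(cov)), target = target,
       nCytosines = nC)
}

# ---------------------------------------------------------------------------
# Observable emission

## Per-position methylation target vector for one genome, honouring the
## copy-level profile plus window-level knockout structure.
methTargetVector <- function(chromLen, profile, genotype, chromatin,
                             windowSize = 100L, seed = 1L) {
  target <- numeric(chromLen)
  if (nrow(profile) == 0L) return(target)
  genotype <- normalizeGenotype(genotype)
  for (i in seq_len(nrow(profile))) {
    span <- profile$start[i]:profile$end[i]
    tg <- rep(profile$target[i], length(span))
    if (!genePresent("hda-1", genotype) &&
        profile$state[i] == "constitutive") {
      # a fixed fraction of established windows depends on HDA-1 entirely
      nWin <- ceiling(length(span) / windowSize)
      winOf <- ((span - profile$start[i]) %/% windowSize) + 1L
      set.seed(deriveSeed(seed, "hda1dep", profile$family[i],
                          profile$copy[i], i))
      nDep <- round(chromatin$hda1DependentFraction * nWin)
      dep <- sample.int(nWin, nDep)
      tg[winOf %in% dep] <- 0
    } else if ((!genePresent("hda-2", genotype) ||
                !genePresent("hda-3", genotype)) &&
               profile$state[i] == "constitutive") {
      tg <- tg * chromatin$hda23Factor
    }
    if (!genePresent("dim-2", genotype)) tg[] <- 0
    target[span] <- tg
  }
  if (!genePresent("dim-2", genotype)) target[] <- 0
  target
}

## Pileup emission for one genome (list of char chromosomes) against a
## reference genome defining the `ref` column.
emitPileupTable <- function(genomeChars, refChars, depth, errorRate,
                            regions = NULL) {
  out <- vector("list", length(genomeChars))
  names(out) <- names(genomeChars)
  for (ch in names(genomeChars)) {
    v <- strsplit(genomeChars[[ch]], "")[[1]]
    rv <- strsplit(refChars[[ch]], "")[[1]]
    pos <- seq_along(v)
    if (!is.null(regions)) {
      sel <- regions[as.character(seqnames(regions)) == ch]
      if (length(sel) == 0L) next
      keep <- sort(unique(unlist(lapply(seq_along(sel), function(i)
        start(sel)[i]:end(sel)[i]))))
      keep <- keep[keep >= 1L & keep <= length(v)]
      pos <- keep
      v <- v[keep]; rv <- rv[keep]
    }
    n <- length(pos)
    dp <- rpois(n, depth)
    nerr <- rbinom(n, dp, errorRate)
    e1 <- rbinom(n, nerr, 1 / 3)
    e2 <- rbinom(n, nerr - e1, 1 / 2)
    e3 <- nerr - e1 - e2
    counts <- matrix(0L, n, 4L, dimnames = list(NULL, .BASES))
    trueIdx <- match(v, .BASES)
    othersIdx <- rbind((trueIdx %% 4L) + 1L,
                       ((trueIdx + 1L) %% 4L) + 1L,
                       ((trueIdx + 2L) %% 4L) + 1L)
    counts[cbind(seq_len(n), trueIdx)] <- dp - nerr
    counts[cbind(seq_len(n), othersIdx[1, ])] <-
      counts[cbind(seq_len(n), othersIdx[1, ])] + e1
    counts[cbind(seq_len(n), othersIdx[2, ])] <-
      counts[cbind(seq_len(n), othersIdx[2, ])] + e2
    counts[cbind(seq_len(n), othersIdx[3, ])] <-
      counts[cbind(seq_len(n), othersIdx[3, ])] + e3
    plus <- matrix(rbinom(length(counts), as.vector(counts), 0.5), n, 4L)
    minus <- counts - plus
    dt <- data.table::data.table(
      chrom = ch, pos = pos, ref = rv,
      A_plus = plus[, 1], A_minus = minus[, 1],
      C_plus = plus[, 2], C_minus = minus[, 2],
      G_plus = plus[, 3], G_minus = minus[, 3],
      T_plus = plus[, 4], T_minus = minus[, 4],
      qual = pmax(0, round(rnorm(n, 60, 3))))
    out[[ch]] <- dt
  }
  data.table::rbindlist(out[!vapply(out, is.null, logical(1))])
}

## Bisulfite emission for one genome given a per-position target list.
emitBisulfiteTable <- function(genomeChars, targetList, depth,
                               regions = NULL) {
  out <- list()
  for (ch in names(genomeChars)) {
    v <- strsplit(genomeChars[[ch]], "")[[1]]
    idx <- which(v == "C" | v == "G")
    if (!is.null(regions)) {
      sel <- regions[as.character(seqnames(regions)) == ch]
      if (length(sel) == 0L) next
      keep <- sort(unique(unlist(lapply(seq_along(sel), function(i)
        start(sel)[i]:end(sel)[i]))))
      keep <- keep[keep >= 1L & keep <= length(v)]
      idx <- idx[idx %in% keep]
    }
    if (!length(idx)) next
    tg <- targetList[[ch]][idx]
    cov <- rpois(length(idx), depth)
    meth <- rbinom(length(idx), cov, tg)
    out[[ch]] <- data.table::data.table(
      chrom = ch, pos = idx,
      strand = ifelse(v[idx] == "C", "+", "-"),
      meth = meth, unmeth = cov - meth)
  }
  data.table::rbindlist(out)
}

#' Emit sequencing observables for one spore
#'
#' Produces (i) a per-site pileup table with per-allele, per-strand read
#' counts at mean depth `depth` and per-base error rate `errorRate`, with
#' the `ref` column taken from parent 1 (the reference genome of the
#' simulation), and (ii) a per-cytosine bisulfite count table in which the
#' methylated count is Binomial(coverage, window target level) under the
#' spore's chromatin profile. A dim-2-null genotype emits methylated
#' count 0 at every cytosine.
#'
#' @param cross A [RipCross-class].
#' @param spore Spore index.
#' @param depth Mean depth (default: configuration depth).
#' @param errorRate Per-base error rate (default: configuration value).
#' @param seed Seed.
#' @param regions Optional `GRanges` restricting emission.
#' @return List with `pileup` and `bisulfite` `data.table`s.
#' @export
emitObservables <- function(cross, spore,
                            depth = cross@parents@config@depth,
                            errorRate = cross@parents@config@errorRate,
                            seed = 1L, regions = NULL) {
  if (depth <= 0) stop("depth must be positive")
  if (errorRate < 0 || errorRate >= 0.5) stop("errorRate must be in [0, 0.5)")
  config <- cross@parents@config
  set.seed(deriveSeed(seed, "observe", spore))
  genome <- asChromList(sporeGenome(cross, spore))
  ref <- asChromList(cross@parents@genome1)
  pile <- emitPileupTable(genome, ref, depth, errorRate, regions)
  sp <- cross@spores[[spore]]
  prof <- sp$meth
  if (nrow(prof)) {
    # restrict the profile to copies the spore actually carries
    ann <- as.data.frame(duplicateAnnotation(cross@parents))
    carried <- vapply(seq_len(nrow(prof)), function(i) {
      a <- ann[ann$family == prof$family[i] & ann$copy == prof$copy[i], ]
      a$presence == "both" || a$presence == sp$origin[[prof$chrom[i]]]
    }, logical(1))
    prof <- prof[carried, , drop = FALSE]
  }
  targets <- lapply(names(genome), function(ch) {
    methTargetVector(nchar(genome[[ch]]),
                     prof[prof$chrom == ch, , drop = FALSE],
                     cross@genotype, config@chromatin,
                     seed = deriveSeed(seed, "meth", spore, ch))
  })
  names(targets) <- names(genome)
  bs <- emitBisulfiteTable(genome, targets, depth, regions)
  list(pileup = pile, bisulfite = bs)
}

#' Emit a parental (vegetative) bisulfite methylome
#'
#' Emits per-cytosine bisulfite counts for parent 1 at the annotated
#' parental methylation levels, optionally after a vegetative knockout:
#' `hda-1` collapses an exact fraction (`hda1DependentFraction`) of
#' constitutive windows to zero, `hda-2`/`hda-3` reduce constitutive
#' levels uniformly, and `dim-2` zeroes everything.
#'
#' @param parents A [ParentalPair-class].
#' @param knockout Genes knocked out vegetatively (default none).
#' @param depth Mean depth per cytosine.
#' @param seed Seed; the choice of HDA-1-dependent windows is derived from
#'   it, so wild-type and knockout emissions at the same seed share the
#'   same dependent-window set.
#' @param windowSize Window size (bp) for the dependent-window structure.
#' @return A bisulfite count `data.table` (`chrom`, `pos`, `strand`,
#'   `meth`, `unmeth`).
#' @export
parentMethylome <- function(parents, knockout = character(), depth = 40,
                            seed = 1L, windowSize = 100L) {
  knockout <- normalizeGenotype(knockout)
  config <- parents@config
  set.seed(deriveSeed(seed, "parentbs", paste(knockout, collapse = ";")))
  genome <- asChromList(parents@genome1)
  ann <- as.data.frame(duplicateAnnotation(parents))
  ann <- ann[ann$presence %in% c("both", "p1"), , drop = FALSE]
  prof <- data.frame(family = ann$family, copy = ann$copy,
                     chrom = as.character(ann$seqnames),
                     start = ann$start, end = ann$end,
                     state = ifelse(ann$class %in% c("euchromatic", "linker"),
                                    "euchromatic", ann$class),
                     target = ann$parentMeth, stringsAsFactors = FALSE)
  targets <- lapply(names(genome), function(ch) {
    methTargetVector(nchar(genome[[ch]]),
                     prof[prof$chrom == ch, , drop = FALSE],
                     knockout, config@chromatin, windowSize = windowSize,
                     seed = deriveSeed(seed, "pdep", ch))
  })
  names(targets) <- names(genome)
  emitBisulfiteTable(genome, targets, depth)
}
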