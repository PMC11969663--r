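#' @import methods
#' @importFrom GenomicRanges GRanges start end width seqnames findOverlaps
#'   mcols mcols<- reduce
#' @importFrom IRanges IRanges successiveIRanges overlapsAny
#' @importFrom S4Vectors queryHits subjectHits DataFrame
#' @importFrom Biostrings DNAString DNAStringSet pairwiseAlignment nmatch
#'   writeXStringSet readDNAStringSet reverseComplement pattern subject
#'   aligned nucleotideSubstitutionMatrix PDict vcountPDict nchar
NULL

.CHROMATIN_STATES <- c("euchromatic", "transitional", "constitutive",
                       "silenced-null")
.DUP_KINDS <- c("R-L-R", "dispersed-pair", "transposon-pair")
.DISTANCE_CATEGORIES <- c("lt5kb", "kb5to300", "gt300kb", "interchromosomal")

# ---------------------------------------------------------------------------
# IntensityModel

#' Per-chromatin-class RIP intensity model
#'
#' Holds, for each chromatin class, three nonnegative coefficients giving
#' the expected number of RIP mutations per affected spore per kb of
#' duplicate that require (i) RID only, (ii) DIM-2 only, (iii) both
#' methyltransferases (the synergistic component). The wild-type intensity
#' of a class is the row sum; a rid/dim-2 double deletion always has
#' intensity zero.
#'
#' @slot coefficients Numeric matrix, one row per chromatin class, columns
#'   `rid`, `dim2`, `syn`.
#' @export
setClass("IntensityModel",
         representation(coefficients = "matrix"))

setValidity("IntensityModel", function(object) {
  m <- object@coefficients
  if (!is.numeric(m) || is.null(rownames(m)))
    return("coefficients must be a numeric matrix with class rownames")
  if (!identical(colnames(m), c("rid", "dim2", "syn")))
    return("coefficient columns must be rid, dim2, syn")
  if (any(m < 0)) return("intensity coefficients must be nonnegative")
  TRUE
})

#' Construct an intensity model
#'
#' @param coefficients Matrix as described in [IntensityModel-class].
#' @return An [IntensityModel-class] object.
#' @export
intensityModel <- function(coefficients) {
  new("IntensityModel", coefficients = coefficients)
}

#' @describeIn intensityModel Chromatin classes known to the model.
#' @param model An `IntensityModel`.
#' @export
chromatinClasses <- function(model) rownames(model@coefficients)

#' @describeIn intensityModel Coefficient matrix accessor.
#' @export
intensityCoefficients <- function(model) model@coefficients

setMethod("show", "IntensityModel", function(object) {
  cat("IntensityModel for", nrow(object@coefficients), "chromatin classes",
      "(mutations / affected spore / kb)\n")
  print(round(object@coefficients, 4))
})

# ---------------------------------------------------------------------------
# DuplicateSpec

#' Specification of a planted duplicate family
#'
#' Describes one duplicate family to plant into the simulated parental
#' genomes: an artificial repeat-linker-repeat (R-L-R) tester, an unlinked
#' two-copy transposon pair split between the parents, or a dispersed
#' historically-methylated pair shared by both parents.
#'
#' @slot family Family name (unique within a configuration).
#' @slot kind One of `"R-L-R"`, `"dispersed-pair"`, `"transposon-pair"`.
#' @slot copyLength Length of each repeat copy in bp.
#' @slot identity Pairwise identity target of the two copies, in (0, 1].
#' @slot linkerLength Linker length in bp (R-L-R only, 0 otherwise).
#' @slot atFraction AT composition target of the planted copies (NA keeps
#'   the genomic background composition).
#' @slot placements data.frame with columns `chrom`, `start` (1-based),
#'   `copy`, `presence` (`"both"`, `"p1"` or `"p2"`), `class` (chromatin
#'   class) and `parentMeth` (parental methylation level of the copy).
#' @export
setClass("DuplicateSpec",
         representation(family = "character", kind = "character",
                        copyLength = "integer", identity = "numeric",
                        linkerLength = "integer", atFraction = "numeric",
                        placements = "data.frame"))

setValidity("DuplicateSpec", function(object) {
  if (!object@kind %in% .DUP_KINDS)
    return(paste("kind must be one of:", paste(.DUP_KINDS, collapse = ", ")))
  if (object@copyLength <= 0L) return("copyLength must be positive")
  if (object@identity <= 0 || object@identity > 1)
    return("identity target must be in (0, 1]")
  need <- c("chrom", "start", "copy", "presence", "class", "parentMeth")
  if (!all(need %in% names(object@placements)))
    return(paste("placements must have columns:", paste(need, collapse = ", ")))
  if (!all(object@placements$class %in% c(.CHROMATIN_STATES, "linker")))
    return("unknown chromatin class in placements")
  if (object@kind == "R-L-R" && object@linkerLength <= 0L)
    return("R-L-R specs need a positive linker length")
  TRUE
})

#' Construct a duplicate-family specification
#'
#' @param family Family name.
#' @param kind `"R-L-R"`, `"dispersed-pair"` or `"transposon-pair"`.
#' @param copyLength Repeat copy length (bp). Defaults: 802 for R-L-R
#'   (the classical tester geometry), 11000 for transposon pairs.
#' @param identity Pairwise identity target of the two copies.
#' @param linkerLength Linker length (bp), R-L-R only; default 729.
#' @param atFraction AT composition target for the planted copies
#'   (`NA` = genomic background).
#' @param chrom,start Chromosome and 1-based start per copy. For R-L-R a
#'   single placement holds the whole R-L-R cassette.
#' @param presence `"both"`, `"p1"` or `"p2"` per copy.
#' @param class Chromatin class per copy.
#' @param parentMeth Parental methylation level per copy.
#' @return A [DuplicateSpec-class] object.
#' @export
duplicateSpec <- function(family, kind, chrom, start,
                          copyLength = if (kind == "R-L-R") 802L else 11000L,
                          identity = 1, linkerLength = if (kind == "R-L-R") 729L else 0L,
                          atFraction = NA_real_,
                          presence = "both", class = "euchromatic",
                          parentMeth = 0) {
  n <- length(chrom)
  pl <- data.frame(chrom = chrom, start = as.integer(start),
                   copy = if (kind == "R-L-R") "cassette" else c("A", "B")[seq_len(n)],
                   presence = rep_len(presence, n),
                   class = rep_len(class, n),
                   parentMeth = rep_len(parentMeth, n),
                   stringsAsFactors = FALSE)
  new("DuplicateSpec", family = family, kind = kind,
      copyLength = as.integer(copyLength), identity = identity,
      linkerLength = as.integer(linkerLength), atFraction = atFraction,
      placements = pl)
}

setMethod("show", "DuplicateSpec", function(object) {
  cat(sprintf("DuplicateSpec '%s' (%s): %d bp copies, identity %.3f\n",
              object@family, object@kind, object@copyLength, object@identity))
})

# ---------------------------------------------------------------------------
# RipSimConfig

#' Simulation configuration
#'
#' Bundles everything the cross simulator needs: chromosome sizes, the
#' duplicate families to plant, the RIP intensity model, the chromatin
#' state-machine parameters, the per-spore RIP event probabilities, and
#' sequencing parameters for the emitted observables.
#'
#' @slot chromLengths Named integer vector of chromosome lengths (bp).
#' @slot dupSpecs List of [DuplicateSpec-class] objects.
#' @slot intensity An [IntensityModel-class].
#' @slot chromatin Named list of state-machine parameters (see
#'   [defaultChromatinParams()]).
#' @slot pEvent Per-spore RIP event probability for unlinked pairs.
#' @slot pEventLinked Per-spore RIP event probability for linked (R-L-R)
#'   constructs.
#' @slot depth Mean sequencing depth of emitted pileups/bisulfite counts.
#' @slot errorRate Per-base sequencing error rate.
#' @slot baseAT AT fraction of the genomic background.
#' @slot overdispersion Negative-binomial size for per-event mutation
#'   counts (`Inf` = Poisson).
#' @slot clusterParams Clustered-placement knobs: `centersPerMutation`
#'   (cluster centres drawn as 1 + Poisson(n * centersPerMutation)) and
#'   `offsetMean` (geometric mean offset from centre, bp).
#' @slot seed Default master seed.
#' @export
setClass("RipSimConfig",
         representation(chromLengths = "integer", dupSpecs = "list",
                        intensity = "IntensityModel", chromatin = "list",
                        pEvent = "numeric", pEventLinked = "numeric",
                        depth = "numeric", errorRate = "numeric",
                        baseAT = "numeric", overdispersion = "numeric",
                        clusterParams = "list", seed = "integer"))

setValidity("RipSimConfig", function(object) {
  if (length(object@chromLengths) == 0L || any(object@chromLengths <= 0L))
    return("all chromosome lengths must be positive")
  if (is.null(names(object@chromLengths)))
    return("chromLengths must be named")
  for (p in c(object@pEvent, object@pEventLinked))
    if (p < 0 || p > 1) return("event probabilities must be in [0, 1]")
  if (object@depth <= 0) return("depth must be positive")
  if (object@errorRate < 0 || object@errorRate >= 0.5)
    return("errorRate must be in [0, 0.5)")
  if (!all(vapply(object@dupSpecs, is, logical(1), "DuplicateSpec")))
    return("dupSpecs must be DuplicateSpec objects")
  TRUE
})

setMethod("show", "RipSimConfig", function(object) {
  cat("RipSimConfig:", length(object@chromLengths), "chromosomes (",
      sum(object@chromLengths), "bp ),", length(object@dupSpecs),
      "duplicate families\n")
  cat("  pEvent =", object@pEvent, " pEventLinked =", object@pEventLinked,
      " depth =", object@depth, " errorRate =", object@errorRate, "\n")
})

# ---------------------------------------------------------------------------
# ParentalPair

#' A pair of haploid parental genomes with duplicate annotations
#'
#' @slot genome1,genome2 `DNAStringSet` of the two haploid parents. The two
#'   genomes share chromosome structure and coordinates; loci carried by a
#'   single parent hold unrelated background sequence in the other parent.
#' @slot duplicates `GRanges` of planted duplicate copies with metadata
#'   columns `family`, `kind`, `copy`, `class`, `parentMeth`, `presence`.
#' @slot config The generating [RipSimConfig-class].
#' @export
setClass("ParentalPair",
         representation(genome1 = "DNAStringSet", genome2 = "DNAStringSet",
                        duplicates = "GRanges", config = "RipSimConfig"))

setValidity("ParentalPair", function(object) {
  if (!identical(names(object@genome1), names(object@genome2)))
    return("parents must share chromosome names")
  if (!identical(Biostrings::width(object@genome1),
                 Biostrings::width(object@genome2)))
    return("parents must share chromosome lengths")
  TRUE
})

#' @describeIn ParentalPair-class Genome of one parent (`which` is 1 or 2,
#'   or `"p1"`/`"p2"`).
#' @param object,x A `ParentalPair`.
#' @param which Parent selector.
#' @export
parentGenome <- function(x, which = 1) {
  w <- if (is.character(which)) match(which, c("p1", "p2")) else which
  if (is.na(w) || !w %in% 1:2) stop("which must be 1, 2, 'p1' or 'p2'")
  if (w == 1) x@genome1 else x@genome2
}

#' @describeIn ParentalPair-class Planted duplicate annotation (`GRanges`).
#' @export
duplicateAnnotation <- function(x) x@duplicates

setMethod("show", "ParentalPair", function(object) {
  cat("ParentalPair:", length(object@genome1), "chromosomes,",
      sum(Biostrings::width(object@genome1)), "bp per parent;",
      length(unique(object@duplicates$family)), "duplicate families\n")
})

# ---------------------------------------------------------------------------
# RipCross

#' Result of one simulated sexual cross
#'
#' @slot spores List of per-spore records (id, tetrad, origin chromosome
#'   assignment, RIP events per family, chromatin profile).
#' @slot truth `data.frame` of true mutations: `spore`, `chrom`, `pos`
#'   (1-based), `ref`, `alt`, `family`, `copy`, `class`.
#' @slot parents The [ParentalPair-class] that was crossed.
#' @slot genotype Canonical genotype (deleted genes) of the cross.
#' @slot generation Generation index of the cross.
#' @export
setClass("RipCross",
         representation(spores = "list", truth = "data.frame",
                        parents = "ParentalPair", genotype = "character",
                        generation = "integer"))

#' @describeIn RipCross-class Number of spores in the cross.
#' @param x A `RipCross`.
#' @export
nSpores <- function(x) length(x@spores)

#' @describeIn RipCross-class True mutation table.
#' @export
truthMutations <- function(x) x@truth

#' @describeIn RipCross-class Per-spore records.
#' @export
sporeInfo <- function(x) x@spores

setMethod("show", "RipCross", function(object) {
  gt <- if (length(object@genotype)) paste(object@genotype, collapse = ";")
        else "wild type"
  cat(sprintf("RipCross: %d spores (%d tetrads), genotype %s, %d true mutations\n",
              length(object@spores), length(object@spores) %/% 4L, gt,
              nrow(object@truth)))
})

# ---------------------------------------------------------------------------
# RipLineage

#' A multi-generation crossing lineage followed at a young duplicate
#'
#' Tracks the chromatin state, methylation target and accumulating RIP
#' mutations of one duplicate copy through repeated crosses to a naive
#' partner (the progressive heterochromatin-formation design).
#'
#' @slot trajectory `data.frame` with one row per generation: `generation`,
#'   `state`, `target`, `atFraction`, `newMutations`.
#' @slot sequence Final sequence of the followed copy (character).
#' @slot genotype Canonical genotype of the crossing background.
#' @slot family Family name of the followed duplicate.
#' @export
setClass("RipLineage",
         representation(trajectory = "data.frame", sequence = "character",
                        genotype = "character", family = "character"))

setMethod("show", "RipLineage", function(object) {
  cat("RipLineage over", nrow(object@trajectory), "generations (family",
      object@family, ")\n")
  print(object@trajectory, row.names = FALSE)
})

#' @describeIn RipLineage-class Generation-by-generation trajectory.
#' @param x A `RipLineage`.
#' @export
lineageTrajectory <- function(x) x@trajectory
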