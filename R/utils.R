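# Internal helpers: RNG plumbing, sequence generation, genotype handling.

#' Derive a reproducible child seed from a master seed
#'
#' A single user-facing seed deterministically fans out into per-stage,
#' per-sample seeds so that any stage of a run can be reproduced in
#' isolation. The derivation is a small integer hash of the master seed and
#' a label; results stay in the positive 32-bit signed range.
#'
#' @param seed Integer master seed.
#' @param ... Labels (character or integer) identifying the stage/sample.
#' @return A single integer seed.
#' @export
deriveSeed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  labels <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(labels)) h <- (h * 131 + ch) %% 1048573
  as.integer((abs(seed) %% 65011 + 1) * 17737 %% 2147483629 + h * 977) %% 2147483629L
}

#' @importFrom stats rbinom rgeom rnbinom rnorm rpois runif pt
#' @import data.table
NULL

utils::globalVariables(c(
  "kid", "pos", "win", "orient", "N", "winA", "winB", "posA", "posB",
  "chromA", "chromB", "wd", "seg", "nSeeds", "posAmin", "posAmax",
  "posBmin", "posBmax", "i.win", "i.pos", "d", "dMed", "winAlo", "winAhi", "chrom", "start", "end", "meth",
  "unmeth", "coverage", "level", "len", "x.pos", "i.index"))

.BASES <- c("A", "C", "G", "T")

## Random DNA sequence with a binomially-sampled AT composition.
randomSequence <- function(n, at = 0.5) {
  p <- c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)
  paste(sample(.BASES, n, replace = TRUE, prob = p), collapse = "")
}

## Random DNA sequence whose AT count is exact (round(n * at)), used for
## planted duplicate copies where the composition itself is asserted.
randomSequenceExactAT <- function(n, at = 0.5) {
  nat <- round(n * at)
  pool <- c(sample(c("A", "T"), nat, replace = TRUE),
            sample(c("G", "C"), n - nat, replace = TRUE))
  paste(sample(pool), collapse = "")
}

## Fraction of A/T bases in a sequence (character scalar).
atFraction <- function(seq) {
  v <- strsplit(seq, "")[[1]]
  mean(v %in% c("A", "T"))
}

## Introduce round((1 - identity) * n) random substitutions so that the
## returned copy has the requested global identity to `seq`.
mutateToIdentity <- function(seq, identity) {
  if (identity <= 0 || identity > 1)
    stop("identity target must be in (0, 1]")
  v <- strsplit(seq, "")[[1]]
  k <- round((1 - identity) * length(v))
  if (k == 0L) return(seq)
  pos <- sample(length(v), k)
  v[pos] <- vapply(v[pos],
                   function(b) sample(setdiff(.BASES, b), 1),
                   character(1), USE.NAMES = FALSE)
  paste(v, collapse = "")
}

.KNOWN_GENES <- c("rid", "dim-2", "hda-1", "hda-2", "hda-3")

#' Normalise a genotype specification
#'
#' A genotype is the set of genes deleted in both crossing partners, given
#' as a character vector; the empty vector is wild type. Synonyms without
#' the hyphen (e.g. `"dim2"`) are accepted.
#'
#' @param genotype Character vector of deleted genes.
#' @return Canonical character vector (subset of
#'   `c("rid", "dim-2", "hda-1", "hda-2", "hda-3")`).
#' @export
normalizeGenotype <- function(genotype) {
  if (length(genotype) == 0L) return(character(0))
  g <- tolower(gsub("(dim|hda)([0-9])", "\\1-\\2", genotype))
  bad <- setdiff(g, .KNOWN_GENES)
  if (length(bad))
    stop("unknown genotype flag(s): ", paste(bad, collapse = ", "))
  unique(g)
}

## TRUE when a gene product is present (i.e. not deleted).
genePresent <- function(gene, genotype) !(gene %in% genotype)

## Split a character genome into a named list of character chromosomes.
asChromList <- function(genome) {
  if (is(genome, "DNAStringSet")) {
    out <- as.character(genome)
    names(out) <- names(genome)
    return(out)
  }
  if (is.character(genome)) {
    if (is.null(names(genome)) && length(genome))
      names(genome) <- paste0("chr", seq_along(genome))
    return(genome)
  }
  stop("genome must be a DNAStringSet or a named character vector")
}
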