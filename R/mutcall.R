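# Parent-offspring mutation identification for haploid crosses: candidate
# calling from trio pileups, the core filter cascade, automated proxies
# for manual artifact checks, and a consensus mode for duplicated loci.

.PILEUP_COLS <- c("chrom", "pos", "ref", "A_plus", "A_minus", "C_plus",
                  "C_minus", "G_plus", "G_minus", "T_plus", "T_minus",
                  "qual")

## per-allele totals and strand counts from a pileup data.table
alleleCounts <- function(p) {
  list(tot = cbind(A = p$A_plus + p$A_minus, C = p$C_plus + p$C_minus,
                   G = p$G_plus + p$G_minus, T = p$T_plus + p$T_minus),
       plus = cbind(A = p$A_plus, C = p$C_plus, G = p$G_plus, T = p$T_plus),
       minus = cbind(A = p$A_minus, C = p$C_minus, G = p$G_minus,
                     T = p$T_minus))
}

#' Call candidate offspring-specific variants from trio pileups
#'
#' Emits a candidate at every site where the offspring majority allele
#' differs from the reference base and is essentially absent from both
#' parental pileups (fewer than `parentCallMax` supporting reads per
#' parent; borderline parental support below that bound is screened later
#' by [exclusionScreen()]). Offspring sites with a second supported allele
#' (minor fraction >= `hetFraction` at depth >= `hetMinDepth`) are emitted
#' flagged heterozygous-like.
#'
#' @param parent1,parent2,offspring Pileup tables (see [readPileup()] for
#'   the column dialect) covering the same coordinate space.
#' @param sample Sample id recorded in the output.
#' @param parentCallMax Parental read support at or above which the allele
#'   counts as present in that parent (default 5).
#' @param hetFraction,hetMinDepth Heterozygous-like flag thresholds.
#' @return data.frame of candidates with evidence fields (depths, parental
#'   alt support, strand split of alt reads, quality, `hetLike`).
#' @export
callCandidates <- function(parent1, parent2, offspring, sample = "offspring",
                           parentCallMax = 5L, hetFraction = 0.2,
                           hetMinDepth = 10L) {
  for (p in list(parent1, parent2, offspring))
    if (!all(.PILEUP_COLS %in% names(p)))
      stop("pileup tables must have columns: ",
           paste(.PILEUP_COLS, collapse = ", "))
  keyO <- paste(offspring$chrom, offspring$pos)
  key1 <- paste(parent1$chrom, parent1$pos)
  key2 <- paste(parent2$chrom, parent2$pos)
  if (!identical(keyO, key1) || !identical(keyO, key2))
    stop("pileup tables do not cover the same coordinate space")
  co <- alleleCounts(offspring)
  c1 <- alleleCounts(parent1)
  c2 <- alleleCounts(parent2)
  depthO <- rowSums(co$tot)
  # candidate allele: the best-supported non-reference allele; a site is
  # a candidate when it is supported at least as well as the reference
  # (a ref/alt tie is a heterozygous-like candidate, not a ref call)
  refIdx <- match(offspring$ref, .BASES)
  nonref <- co$tot
  nonref[cbind(seq_len(nrow(nonref)), refIdx)] <- -1L
  maj <- .BASES[max.col(nonref, ties.method = "first")]
  altCount <- nonref[cbind(seq_len(nrow(nonref)), match(maj, .BASES))]
  refCount <- co$tot[cbind(seq_len(nrow(co$tot)), refIdx)]
  isCand <- depthO > 0 & altCount >= pmax(refCount, 1L)
  if (!any(isCand))
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      sample = character(0), depth = integer(0),
                      depthP1 = integer(0), depthP2 = integer(0),
                      altP1 = integer(0), altP2 = integer(0),
                      altPlus = integer(0), altMinus = integer(0),
                      qual = numeric(0), hetLike = logical(0),
                      stringsAsFactors = FALSE))
  emptyOut <- data.frame(chrom = character(0), pos = integer(0),
                         ref = character(0), alt = character(0),
                         sample = character(0), depth = integer(0),
                         depthP1 = integer(0), depthP2 = integer(0),
                         altP1 = integer(0), altP2 = integer(0),
                         altPlus = integer(0), altMinus = integer(0),
                         qual = numeric(0), hetLike = logical(0),
                         stringsAsFactors = FALSE)
  idx <- which(isCand)
  altIdx <- match(maj[idx], .BASES)
  pick <- cbind(idx, altIdx)
  altP1 <- c1$tot[pick]
  altP2 <- c2$tot[pick]
  keep <- altP1 < parentCallMax & altP2 < parentCallMax
  idx <- idx[keep]; altIdx <- altIdx[keep]; pick <- pick[keep, , drop = FALSE]
  if (!length(idx)) return(emptyOut)
  secondBest <- apply(co$tot[idx, , drop = FALSE], 1, function(r)
    sort(r, decreasing = TRUE)[2])
  hetLike <- depthO[idx] >= hetMinDepth &
    secondBest / pmax(1, depthO[idx]) >= hetFraction
  data.frame(chrom = offspring$chrom[idx], pos = offspring$pos[idx],
             ref = offspring$ref[idx], alt = .BASES[altIdx],
             sample = sample, depth = depthO[idx],
             depthP1 = rowSums(c1$tot)[idx], depthP2 = rowSums(c2$tot)[idx],
             altP1 = c1$tot[pick], altP2 = c2$tot[pick],
             altPlus = co$plus[pick], altMinus = co$minus[pick],
             qual = offspring$qual[idx], hetLike = hetLike,
             stringsAsFactors = FALSE)
}

#' Apply the core variant filters
#'
#' Adds named pass/fail verdict columns: `DEPTH` (parents and offspring
#' all at depth >= `minDepth`), `HAPLOID` (a single supported allele in
#' the offspring), `QUAL` (site quality strictly greater than `minQual`)
#' and `STRAND` (at least one alt read on each strand). Verdicts are
#' computed independently; `PASS` is their conjunction.
#'
#' @param candidates Output of [callCandidates()].
#' @param minDepth Minimum per-sample depth (default 5).
#' @param minQual Quality threshold, strict (default 30).
#' @return The candidate table with verdict columns and `PASS`.
#' @export
applyCoreFilters <- function(candidates, minDepth = 5L, minQual = 30) {
  candidates$DEPTH <- candidates$depth >= minDepth &
    candidates$depthP1 >= minDepth & candidates$depthP2 >= minDepth
  candidates$HAPLOID <- !candidates$hetLike
  candidates$QUAL <- candidates$qual > minQual
  candidates$STRAND <- candidates$altPlus >= 1L & candidates$altMinus >= 1L
  candidates$PASS <- candidates$DEPTH & candidates$HAPLOID &
    candidates$QUAL & candidates$STRAND
  candidates
}

## Homopolymer runs of length >= minRun in a genome; returns a GRanges.
homopolymerRuns <- function(chars, minRun = 6L) {
  out <- list()
  for (ch in names(chars)) {
    r <- rle(strsplit(chars[[ch]], "")[[1]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$lengths >= minRun
    if (any(keep))
      out[[ch]] <- GRanges(ch, IRanges(starts[keep], ends[keep]))
  }
  if (!length(out)) return(GRanges())
  suppressWarnings(do.call(c, unname(out)))
}

#' Screen candidates against common artifact classes
#'
#' Automated proxies for manual variant checks:
#' * `POLYMER` (reject): the variant lies inside or within `adjacency` bp
#'   of a homopolymer run of `homopolymerMin`+ bp (misalignment-prone).
#' * `MAPPING` (flag, not reject): the majority of the `uniquenessK`-mers
#'   overlapping the site occur more than once genome-wide (error-prone
#'   mapping); such variants need confirmation by [consensusCompare()]
#'   since RIP targets are duplicated by definition.
#' * `PARENTAL_SUPPORT` (reject): a parental pileup shows the alt allele
#'   at >= `parentMaxReads` reads or >= `parentMaxFraction` of its depth.
#'
#' @param candidates Candidate table with verdicts
#'   ([applyCoreFilters()]).
#' @param genome Reference genome (`DNAStringSet` or named character).
#' @param homopolymerMin,adjacency Homopolymer run length and adjacency.
#' @param uniquenessK k-mer length for the mapping-uniqueness proxy.
#' @param parentMaxReads,parentMaxFraction Parental-support rejection
#'   thresholds.
#' @return The table with `POLYMER`, `MAPPING`, `PARENTAL_SUPPORT`
#'   columns, updated `PASS`, and a `status` column: `"PASS"`,
#'   `"REJECT"`, or `"CONSENSUS_REQUIRED"` (mapping-flagged but otherwise
#'   passing).
#' @export
exclusionScreen <- function(candidates, genome, homopolymerMin = 6L,
                            adjacency = 2L, uniquenessK = 31L,
                            parentMaxReads = 2L, parentMaxFraction = 0.05) {
  chars <- asChromList(genome)
  n <- nrow(candidates)
  if (n == 0L) {
    candidates$POLYMER <- logical(0)
    candidates$MAPPING <- logical(0)
    candidates$PARENTAL_SUPPORT <- logical(0)
    candidates$status <- character(0)
    return(candidates)
  }
  runs <- homopolymerRuns(chars, homopolymerMin)
  vgr <- GRanges(candidates$chrom, IRanges(candidates$pos, candidates$pos))
  candidates$POLYMER <- overlapsAny(vgr + adjacency, runs)
  # mapping-uniqueness: count genome-wide occurrences (both strands) of
  # every k-mer overlapping the site
  gset <- DNAStringSet(unlist(chars))
  kmerSets <- lapply(seq_len(n), function(i) {
    L <- nchar(chars[[candidates$chrom[i]]])
    starts <- max(1L, candidates$pos[i] - uniquenessK + 1L):
      min(L - uniquenessK + 1L, candidates$pos[i])
    starts <- starts[starts >= 1L]
    substring(chars[[candidates$chrom[i]]], starts,
              starts + uniquenessK - 1L)
  })
  mapping <- logical(n)
  lens <- lengths(kmerSets)
  if (any(lens > 0L)) {
    pd <- PDict(DNAStringSet(unlist(kmerSets[lens > 0L])))
    hits <- rowSums(vcountPDict(pd, gset)) +
      rowSums(vcountPDict(pd, reverseComplement(gset)))
    grp <- rep(which(lens > 0L), lens[lens > 0L])
    mapping[lens > 0L] <- vapply(split(hits > 1L, grp), function(z)
      mean(z) > 0.5, logical(1))
  }
  candidates$MAPPING <- mapping
  candidates$PARENTAL_SUPPORT <-
    candidates$altP1 >= parentMaxReads |
    candidates$altP2 >= parentMaxReads |
    candidates$altP1 / pmax(1L, candidates$depthP1) >= parentMaxFraction |
    candidates$altP2 / pmax(1L, candidates$depthP2) >= parentMaxFraction
  core <- if ("PASS" %in% names(candidates)) candidates$PASS
          else rep(TRUE, n)
  ok <- core & !candidates$POLYMER & !candidates$PARENTAL_SUPPORT
  candidates$PASS <- ok & !candidates$MAPPING
  candidates$status <- ifelse(!ok, "REJECT",
                              ifelse(candidates$MAPPING,
                                     "CONSENSUS_REQUIRED", "PASS"))
  candidates
}

#' Call mutations in a trio end to end
#'
#' Convenience wrapper: [callCandidates()] then [applyCoreFilters()] then
#' [exclusionScreen()].
#'
#' @inheritParams callCandidates
#' @param genome Reference genome for the exclusion screen.
#' @param ... Passed on to the component steps.
#' @return Screened candidate table.
#' @export
callTrio <- function(parent1, parent2, offspring, genome,
                     sample = "offspring", ...) {
  cand <- callCandidates(parent1, parent2, offspring, sample = sample)
  cand <- applyCoreFilters(cand)
  exclusionScreen(cand, genome, ...)
}

#' Assign a progeny locus to a parental allele and extract its mutations
#'
#' Globally aligns a reconstructed progeny locus against both parental
#' alleles, assigns it to the allele with the higher identity, and
#' returns substitutions relative to the assigned allele. Differences
#' between the two parental alleles are never reported as mutations. An
#' identity difference below `minMargin` (0.1 percentage points) is
#' ambiguous and raises an error.
#'
#' @param progeny,alleleA,alleleB Sequences (character or `DNAString`).
#' @param minMargin Minimum identity margin for an unambiguous
#'   assignment, as a fraction (default 0.001).
#' @return List with `allele` (`"A"` or `"B"`), `identity`, and
#'   `mutations` (data.frame `pos`, `ref`, `alt` in assigned-allele
#'   coordinates).
#' @export
consensusCompare <- function(progeny, alleleA, alleleB, minMargin = 0.001) {
  progeny <- as.character(progeny)
  alleleA <- as.character(alleleA)
  alleleB <- as.character(alleleB)
  if (any(nchar(c(progeny, alleleA, alleleB)) == 0L))
    stop("sequences must be non-empty")
  alnOne <- function(allele) {
    pairwiseAlignment(DNAString(progeny), DNAString(allele),
                      substitutionMatrix = .identityScoring(),
                      gapOpening = 10, gapExtension = 4, type = "global")
  }
  alnA <- alnOne(alleleA)
  alnB <- alnOne(alleleB)
  idA <- nmatch(alnA) / nchar(alnA)
  idB <- nmatch(alnB) / nchar(alnB)
  if (abs(idA - idB) < minMargin)
    stop(sprintf(paste("ambiguous allele assignment (identity %.4f vs %.4f);",
                       "manual resolution required"), idA, idB))
  best <- if (idA > idB) alnA else alnB
  pa <- strsplit(as.character(pattern(best)), "")[[1]]
  su <- strsplit(as.character(subject(best)), "")[[1]]
  posAllele <- cumsum(su != "-")
  isSub <- pa != su & pa != "-" & su != "-"
  list(allele = if (idA > idB) "A" else "B",
       identity = max(idA, idB),
       mutations = data.frame(pos = posAllele[isSub], ref = su[isSub],
                              alt = pa[isSub], stringsAsFactors = FALSE))
}
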