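# Windowed duplicate detection: tile the genome into fixed windows, find
# window pairs joined by a pairwise hit above an identity cutoff, label
# Dup/non-Dup windows, and assign physical-distance categories.

#' Tile a genome into fixed non-overlapping windows
#'
#' @param genome `DNAStringSet`, named character vector of chromosome
#'   sequences, or named integer vector of chromosome lengths.
#' @param size Window size in bp (default 500). The terminal remainder of
#'   each chromosome is kept as a shorter window.
#' @return `GRanges` of windows with a metadata column `index` (global
#'   window index).
#' @export
windowGenome <- function(genome, size = 500L) {
  if (size <= 0) stop("window size must be positive")
  lens <- if (is.numeric(genome)) {
    if (is.null(names(genome))) stop("chromosome lengths must be named")
    setNames(as.integer(genome), names(genome))
  } else {
    g <- asChromList(genome)
    setNames(nchar(g), names(g))
  }
  if (length(lens) == 0L) return(GRanges())
  grl <- lapply(names(lens), function(ch) {
    n <- ceiling(lens[[ch]] / size)
    if (n == 0L) return(GRanges())
    starts <- seq.int(1L, by = size, length.out = n)
    GRanges(ch, IRanges(starts, width = pmin(size, lens[[ch]] - starts + 1L)))
  })
  out <- suppressWarnings(do.call(c, grl))
  mcols(out)$index <- seq_along(out)
  out
}

## Scoring for full-span identity: a mild mismatch penalty keeps the local
## alignment extended over the whole homologous span (expected score is
## positive even for unrelated sequence), so the identity denominator is
## the full alignment rather than a trimmed high-scoring island.
.identityScoring <- function() {
  nucleotideSubstitutionMatrix(match = 4, mismatch = -1, baseOnly = TRUE)
}

## Scoring for hit delineation: BLASTN-like rewards/penalties trim
## non-homologous flanks (expected score on random sequence is negative).
.hitScoring <- function() {
  nucleotideSubstitutionMatrix(match = 2, mismatch = -3, baseOnly = TRUE)
}

#' Alignment identity of two sequences
#'
#' Aligns the two sequences (local model with a mild mismatch penalty, so
#' homologous sequences align over their full shared span) and returns
#' matches divided by alignment columns, counting gap columns in the
#' denominator. Unrelated sequences therefore score near the random
#' expectation (~0.4), not the identity of a short exact island.
#'
#' @param a,b Sequences (character or `DNAString`).
#' @return Identity fraction in (0, 1].
#' @export
alignmentIdentity <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  if (nchar(a) == 0L || nchar(b) == 0L)
    stop("sequences must be non-empty")
  aln <- pairwiseAlignment(DNAString(a), DNAString(b),
                           substitutionMatrix = .identityScoring(),
                           gapOpening = 10, gapExtension = 4,
                           type = "local")
  nmatch(aln) / nchar(aln)
}

## k-mer start positions and integer ids for one chromosome (forward).
kmerIds <- function(v, k) {
  code <- match(v, .BASES) - 1L
  y <- stats::filter(code, 4^(0:(k - 1)), sides = 1)
  ids <- as.numeric(y[k:length(y)])
  data.table::data.table(pos = seq_len(length(v) - k + 1L), kid = ids)[!is.na(kid)]
}

.COMP <- c(A = "T", C = "G", G = "C", T = "A")

## Candidate window pairs from shared k-mers; returns a data.table of
## (winA, winB, orient) with per-pair seed counts and seed positions.
seedWindowPairs <- function(chars, windows, k, minSeeds, maxKmerHits,
                            windowSize) {
  # windows come from windowGenome(): a regular tiling, so the window
  # index of a position is arithmetic (per-chromosome offset + pos %/% size)
  winChrom <- as.character(seqnames(windows))
  firstIdx <- vapply(names(chars),
                     function(ch) which(winChrom == ch)[1], integer(1))
  tabs <- list()
  for (ch in names(chars)) {
    v <- strsplit(chars[[ch]], "")[[1]]
    L <- length(v)
    fwd <- kmerIds(v, k)
    fwd[, `:=`(chrom = ch, orient = "+")]
    rcv <- rev(unname(.COMP[v]))
    rc <- kmerIds(rcv, k)
    # forward coordinate of the k-mer whose reverse complement starts at pos
    rc[, pos := L - (pos + k - 1L) + 1L]
    rc[, `:=`(chrom = ch, orient = "-")]
    tabs[[ch]] <- data.table::rbindlist(list(fwd, rc))
    tabs[[ch]][, win := firstIdx[[ch]] + (pos - 1L) %/% as.integer(windowSize)]
  }
  kt <- data.table::rbindlist(tabs)
  counts <- kt[, .N, by = kid]
  keep <- counts[N >= 2L & N <= maxKmerHits, kid]
  kt <- kt[kid %in% keep]
  if (nrow(kt) == 0L) return(NULL)
  fwd <- kt[orient == "+"]
  rc <- kt[orient == "-"]
  # forward-forward candidates
  ff <- fwd[fwd, on = "kid", allow.cartesian = TRUE,
            .(kid, winA = win, posA = pos, winB = i.win, posB = i.pos)]
  ff <- ff[winA < winB]
  ff[, orient := "+"]
  # forward vs reverse-complement candidates (inverted duplicates)
  fr <- fwd[rc, on = "kid", allow.cartesian = TRUE, nomatch = NULL,
            .(kid, winA = win, posA = pos, winB = i.win, posB = i.pos)]
  fr <- fr[winA < winB]
  fr[, orient := "-"]
  cand <- data.table::rbindlist(list(ff, fr))
  if (nrow(cand) == 0L) return(NULL)
  # seeds supporting a genuine pair lie on a consistent alignment
  # diagonal; random double-collisions do not
  cand[, d := data.table::fifelse(orient == "+", posB - posA, posB + posA)]
  seeds <- cand[, {
    o <- order(d)
    dd <- d[o]; pa <- posA[o]; pb <- posB[o]
    run <- cumsum(c(1L, diff(dd) > 20L))
    best <- which.max(tabulate(run))
    keep <- run == best
    list(nSeeds = length(unique(pa[keep])),
         dMed = as.integer(stats::median(dd[keep])),
         posAmin = min(pa[keep]), posAmax = max(pa[keep]),
         posBmin = min(pb[keep]), posBmax = max(pb[keep]))
  }, by = .(winA, winB, orient)]
  seeds[nSeeds >= minSeeds]
}

#' Find duplicate window pairs above an identity cutoff
#'
#' k-mer-seeded candidate detection followed by pairwise alignment:
#' shared-k-mer window pairs are chained along diagonals into candidate
#' segment pairs, each segment pair is scored with [alignmentIdentity()]
#' over its seeded span, and accepted segments (identity strictly greater
#' than `minIdentity`) are delineated with a local alignment whose hit
#' footprint labels every overlapping window pair. Both orientations are
#' searched; mirror duplicates and self-hits are removed.
#'
#' @param genome `DNAStringSet` or named character vector.
#' @param minIdentity Identity cutoff (strictly greater-than; default
#'   0.65).
#' @param windows Optional precomputed [windowGenome()] tiling.
#' @param windowSize Window size when `windows` is NULL.
#' @param k Seed k-mer length (default 11).
#' @param minSeeds Minimum distinct shared k-mers to consider a window
#'   pair (default 2).
#' @param maxKmerHits Skip k-mers occurring more often than this
#'   genome-wide (low-complexity guard; default 64).
#' @return data.frame of duplicate pairs: window coordinates of both
#'   sides, `identity`, `orient`, `gap` (bp between nearest ends, NA for
#'   interchromosomal) and `category`.
#' @export
findDuplicatePairs <- function(genome, minIdentity = 0.65, windows = NULL,
                               windowSize = 500L, k = 11L, minSeeds = 2L,
                               maxKmerHits = 64L) {
  chars <- asChromList(genome)
  if (is.null(windows)) windows <- windowGenome(chars, windowSize)
  else windowSize <- max(width(windows))
  emptyPairs <- data.frame(chromA = character(0), startA = integer(0),
                           endA = integer(0), chromB = character(0),
                           startB = integer(0), endB = integer(0),
                           identity = numeric(0), orient = character(0),
                           gap = numeric(0), category = character(0),
                           stringsAsFactors = FALSE)
  if (length(windows) == 0L) return(emptyPairs)
  seeds <- seedWindowPairs(chars, windows, k, minSeeds, maxKmerHits,
                           windowSize)
  if (is.null(seeds) || nrow(seeds) == 0L) return(emptyPairs)
  winChrom <- as.character(seqnames(windows))
  winStart <- start(windows)
  winEnd <- end(windows)
  seeds[, `:=`(chromA = winChrom[winA], chromB = winChrom[winB])]
  seeds[, wd := data.table::fifelse(orient == "+", winB - winA, winB + winA)]
  data.table::setorder(seeds, chromA, chromB, orient, wd, winA)
  # chain candidate window pairs into segments along diagonals
  seeds[, seg := cumsum(c(1L, (chromA[-1] != chromA[-.N]) |
                               (chromB[-1] != chromB[-.N]) |
                               (orient[-1] != orient[-.N]) |
                               (abs(wd[-1] - wd[-.N]) > 1L) |
                               (abs(winA[-1] - winA[-.N]) > 2L)))]
  segs <- seeds[, .(chromA = chromA[1], chromB = chromB[1],
                    orient = orient[1], dMed = as.integer(stats::median(dMed)),
                    winAlo = min(winA), winAhi = max(winA),
                    aLo = min(posAmin), aHi = max(posAmax) + k - 1L,
                    bLo = min(posBmin), bHi = max(posBmax) + k - 1L),
                by = seg]
  vlist <- lapply(chars, function(s) strsplit(s, "")[[1]])
  pairRows <- list()
  for (i in seq_len(nrow(segs))) {
    sg <- segs[i]
    # degenerate or self-overlapping segments are not duplicates
    if (sg$chromA == sg$chromB && sg$aHi >= sg$bLo && sg$bHi >= sg$aLo) next
    # cheap ungapped identity along the seeded diagonal, over the full
    # window footprint of the segment, discards the spurious
    # double-collision candidates before any alignment is attempted
    xs <- winStart[sg$winAlo]:winEnd[sg$winAhi]
    if (sg$orient == "+") {
      ys <- xs + sg$dMed
      ok <- ys >= 1L & ys <= length(vlist[[sg$chromB]])
      ung <- mean(vlist[[sg$chromA]][xs[ok]] == vlist[[sg$chromB]][ys[ok]])
    } else {
      ys <- sg$dMed + k - 1L - xs
      ok <- ys >= 1L & ys <= length(vlist[[sg$chromB]])
      ung <- mean(vlist[[sg$chromA]][xs[ok]] ==
                    unname(.COMP[vlist[[sg$chromB]][ys[ok]]]))
    }
    if (!length(xs[ok]) || is.na(ung) || ung <= 0.5) next
    seqA <- substring(chars[[sg$chromA]], sg$aLo, sg$aHi)
    seqB <- substring(chars[[sg$chromB]], sg$bLo, sg$bHi)
    if (nchar(seqA) < k || nchar(seqB) < k) next
    if (sg$orient == "-")
      seqB <- paste(rev(unname(.COMP[strsplit(seqB, "")[[1]]])), collapse = "")
    ident <- alignmentIdentity(seqA, seqB)
    if (ident <= minIdentity) next
    # delineate the hit with trimming scoring, padded by one window
    pad <- windowSize
    aLo2 <- max(1L, sg$aLo - pad)
    aHi2 <- min(nchar(chars[[sg$chromA]]), sg$aHi + pad)
    bLo2 <- max(1L, sg$bLo - pad)
    bHi2 <- min(nchar(chars[[sg$chromB]]), sg$bHi + pad)
    sA <- substring(chars[[sg$chromA]], aLo2, aHi2)
    sB <- substring(chars[[sg$chromB]], bLo2, bHi2)
    if (sg$orient == "-")
      sB <- paste(rev(unname(.COMP[strsplit(sB, "")[[1]]])), collapse = "")
    aln <- pairwiseAlignment(DNAString(sA), DNAString(sB),
                             substitutionMatrix = .hitScoring(),
                             gapOpening = 5, gapExtension = 2,
                             type = "local")
    hitAlo <- aLo2 + start(pattern(aln)) - 1L
    hitAhi <- aLo2 + end(pattern(aln)) - 1L
    if (sg$orient == "+") {
      hitBlo <- bLo2 + start(subject(aln)) - 1L
      hitBhi <- bLo2 + end(subject(aln)) - 1L
    } else {
      lenB <- bHi2 - bLo2 + 1L
      hitBlo <- bLo2 + (lenB - end(subject(aln)) + 1L) - 1L
      hitBhi <- bLo2 + (lenB - start(subject(aln)) + 1L) - 1L
    }
    # window pairs along the hit footprint
    wA <- which(winChrom == sg$chromA & winStart <= hitAhi & winEnd >= hitAlo)
    wB <- which(winChrom == sg$chromB & winStart <= hitBhi & winEnd >= hitBlo)
    if (!length(wA) || !length(wB)) next
    map <- if (length(wA) == 1L) rep(wB[1], 1L) else {
      fr <- (seq_along(wA) - 1L) / (length(wA) - 1L)
      if (sg$orient == "-") fr <- 1 - fr
      wB[pmin(length(wB), pmax(1L, round(fr * (length(wB) - 1L)) + 1L))]
    }
    pairRows[[length(pairRows) + 1L]] <- data.frame(
      winA = wA, winB = map, identity = ident, orient = sg$orient,
      stringsAsFactors = FALSE)
  }
  if (!length(pairRows)) return(emptyPairs)
  pr <- do.call(rbind, pairRows)
  # canonical order and mirror removal; keep the best identity per pair
  swap <- pr$winA > pr$winB
  tmp <- pr$winA[swap]; pr$winA[swap] <- pr$winB[swap]; pr$winB[swap] <- tmp
  pr <- pr[pr$winA != pr$winB, , drop = FALSE]
  pr <- pr[order(pr$winA, pr$winB, -pr$identity), , drop = FALSE]
  pr <- pr[!duplicated(pr[, c("winA", "winB")]), , drop = FALSE]
  out <- data.frame(chromA = winChrom[pr$winA], startA = winStart[pr$winA],
                    endA = winEnd[pr$winA], chromB = winChrom[pr$winB],
                    startB = winStart[pr$winB], endB = winEnd[pr$winB],
                    identity = pr$identity, orient = pr$orient,
                    stringsAsFactors = FALSE)
  cd <- categorizeDistance(out)
  out$gap <- cd$gap
  out$category <- cd$category
  rownames(out) <- NULL
  out
}

#' Label windows as duplicate (Dup) or non-duplicate (non-Dup)
#'
#' A window is Dup iff it participates in at least one pair; the operation
#' is idempotent and independent of the pair-list order.
#'
#' @param windows [windowGenome()] tiling.
#' @param pairs Pair table from [findDuplicatePairs()].
#' @return List with `windows` (the input `GRanges` plus a `dup` logical
#'   metadata column), `dupSpan` (total Dup bp) and `dupFraction`.
#' @export
annotateDupWindows <- function(windows, pairs) {
  key <- paste(as.character(seqnames(windows)), start(windows))
  dupKeys <- unique(c(paste(pairs$chromA, pairs$startA),
                      paste(pairs$chromB, pairs$startB)))
  dup <- key %in% dupKeys
  mcols(windows)$dup <- dup
  list(windows = windows,
       dupSpan = sum(width(windows)[dup]),
       dupFraction = sum(width(windows)[dup]) / sum(width(windows)))
}

#' Physical-distance category of duplicate pairs
#'
#' The gap is the number of bp between the nearest ends of the two
#' features on the same chromosome (0 if they overlap); categories are
#' `[0, 5 kb)`, `[5 kb, 300 kb)`, `[300 kb, Inf)` and interchromosomal.
#'
#' @param pairs data.frame with `chromA`, `startA`, `endA`, `chromB`,
#'   `startB`, `endB` (1-based inclusive coordinates).
#' @return data.frame with columns `gap` (NA for interchromosomal) and
#'   `category`.
#' @export
categorizeDistance <- function(pairs) {
  n <- nrow(pairs)
  gap <- rep(NA_real_, n)
  category <- character(n)
  same <- pairs$chromA == pairs$chromB
  g <- pmax(0, pmax(pairs$startA, pairs$startB) -
                 pmin(pairs$endA, pairs$endB) - 1)
  gap[same] <- g[same]
  category[!same] <- "interchromosomal"
  category[same & g < 5000] <- "lt5kb"
  category[same & g >= 5000 & g < 300000] <- "kb5to300"
  category[same & g >= 300000] <- "gt300kb"
  data.frame(gap = gap, category = category, stringsAsFactors = FALSE)
}
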