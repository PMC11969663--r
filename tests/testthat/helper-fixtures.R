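# Shared fixtures, built in code. The default parental pair is cached per
# test session since several files exercise it.

suppressMessages({
  library(GenomicRanges)
  library(IRanges)
})

.fixtureEnv <- new.env()

fixtureParents <- function() {
  if (is.null(.fixtureEnv$parents))
    .fixtureEnv$parents <- buildParentalGenomes(defaultSimConfig(seed = 42L))
  .fixtureEnv$parents
}

fixtureCross <- function(genotype = character(), nTetrads = 3L, seed = 42L) {
  simulateCross(fixtureParents(), genotype, nTetrads, seed)
}

## random sequence helper mirroring the package-internal generator
randSeq <- function(n, at = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)),
        collapse = "")
}

## a perfect-evidence pileup over a chromosome set: every site shows the
## true base at depth `depth`, split depth/2 per strand, quality `qual`
perfectPileup <- function(chars, depth = 40L, qual = 60) {
  half <- depth %/% 2L
  rows <- lapply(names(chars), function(ch) {
    v <- strsplit(chars[[ch]], "")[[1]]
    n <- length(v)
    dt <- data.table::data.table(
      chrom = ch, pos = seq_len(n), ref = v,
      A_plus = 0L, A_minus = 0L, C_plus = 0L, C_minus = 0L,
      G_plus = 0L, G_minus = 0L, T_plus = 0L, T_minus = 0L, qual = qual)
    for (b in c("A", "C", "G", "T")) {
      sel <- v == b
      data.table::set(dt, which(sel), paste0(b, "_plus"), half)
      data.table::set(dt, which(sel), paste0(b, "_minus"), depth - half)
    }
    dt
  })
  data.table::rbindlist(rows)
}

## overwrite the allele evidence at one site of a pileup table
setSite <- function(pileup, chrom, pos, counts = list(), qual = NULL) {
  i <- which(pileup$chrom == chrom & pileup$pos == pos)
  stopifnot(length(i) == 1L)
  for (col in c("A_plus", "A_minus", "C_plus", "C_minus",
                "G_plus", "G_minus", "T_plus", "T_minus"))
    data.table::set(pileup, i, col, 0L)
  for (nm in names(counts)) data.table::set(pileup, i, nm, counts[[nm]])
  if (!is.null(qual)) data.table::set(pileup, i, "qual", qual)
  invisible(pileup)
}
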