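# A small constructed trio over a 600 bp reference exercises the calling
# and filter contracts deterministically.

mkTrio <- function() {
  set.seed(314)
  ref <- randSeq(600)
  # guarantee a C at the probed sites
  v <- strsplit(ref, "")[[1]]
  v[c(100, 200, 300, 400)] <- "C"
  chars <- c(chr1 = paste(v, collapse = ""))
  list(chars = chars,
       p1 = perfectPileup(chars), p2 = perfectPileup(chars),
       off = perfectPileup(chars))
}

test_that("candidates require offspring-specific alleles", {
  tr <- mkTrio()
  # clean candidate: offspring 20x T at a C site, parents clean
  setSite(tr$off, "chr1", 100, list(T_plus = 10L, T_minus = 10L))
  # parental-present: parent 1 carries 6 supporting reads
  setSite(tr$off, "chr1", 200, list(T_plus = 10L, T_minus = 10L))
  setSite(tr$p1, "chr1", 200, list(C_plus = 7L, C_minus = 7L,
                                   T_plus = 3L, T_minus = 3L))
  # heterozygous-like: two supported alleles
  setSite(tr$off, "chr1", 300, list(C_plus = 5L, C_minus = 5L,
                                    T_plus = 5L, T_minus = 5L))
  cand <- callCandidates(tr$p1, tr$p2, tr$off)
  expect_setequal(cand$pos, c(100L, 300L))
  expect_equal(cand$alt[cand$pos == 100], "T")
  expect_false(cand$hetLike[cand$pos == 100])
  expect_true(cand$hetLike[cand$pos == 300])
  # the heterozygous-like candidate is rejected by the core filters
  filt <- applyCoreFilters(cand)
  expect_true(filt$PASS[filt$pos == 100])
  expect_false(filt$HAPLOID[filt$pos == 300])
  expect_false(filt$PASS[filt$pos == 300])
  # coordinate-space mismatch is an error
  expect_error(callCandidates(tr$p1[-1, ], tr$p2, tr$off),
               "coordinate space")
})

test_that("core filters reject low depth, low quality and strand bias", {
  tr <- mkTrio()
  setSite(tr$off, "chr1", 100, list(T_plus = 2L, T_minus = 2L))       # depth 4
  setSite(tr$off, "chr1", 200, list(T_plus = 10L, T_minus = 10L),
          qual = 25)                                                  # qual 25
  setSite(tr$off, "chr1", 300, list(T_plus = 20L))                    # one strand
  setSite(tr$off, "chr1", 400, list(T_plus = 10L, T_minus = 10L))     # clean
  cand <- applyCoreFilters(callCandidates(tr$p1, tr$p2, tr$off))
  expect_false(cand$DEPTH[cand$pos == 100])
  expect_false(cand$QUAL[cand$pos == 200])
  expect_false(cand$STRAND[cand$pos == 300])
  expect_equal(cand$pos[cand$PASS], 400L)
  # verdicts are independent; the final status is their conjunction
  expect_identical(cand$PASS,
                   cand$DEPTH & cand$HAPLOID & cand$QUAL & cand$STRAND)
  # boundary: quality must be strictly greater than 30
  setSite(tr$off, "chr1", 400, list(T_plus = 10L, T_minus = 10L), qual = 30)
  cand30 <- applyCoreFilters(callCandidates(tr$p1, tr$p2, tr$off))
  expect_false(cand30$QUAL[cand30$pos == 400])
})

test_that("the exclusion screen rejects homopolymer-adjacent and
           parental-supported variants and flags duplicated loci", {
  set.seed(7)
  left <- randSeq(250)
  repeatUnit <- randSeq(200)
  # an 8 bp A-run at positions 251..258, then unique sequence, then an
  # exact two-copy 200 bp repeat
  chars <- c(chr1 = paste0(left, "AAAAAAAA", randSeq(150), repeatUnit,
                           randSeq(100), repeatUnit, randSeq(100)))
  v <- strsplit(chars[["chr1"]], "")[[1]]
  p1 <- perfectPileup(chars); p2 <- perfectPileup(chars)
  off <- perfectPileup(chars)
  gc <- which(v %in% c("C", "G"))
  polymerSite <- 260L  # 2 bp from the A-run (position 251..258)
  v[polymerSite] <- "C"
  chars[["chr1"]] <- paste(v, collapse = "")
  p1 <- perfectPileup(chars); p2 <- perfectPileup(chars)
  off <- perfectPileup(chars)
  dupSite <- gc[gc > 470 & gc < 540][1]    # deep inside the first copy
  cleanSite <- gc[gc > 270 & gc < 400][1]  # unique, far from the run
  parSite <- gc[gc > 270 & gc < 400][2]
  alt <- function(b) if (b == "C") "T" else "A"
  for (s in c(polymerSite, dupSite, cleanSite, parSite)) {
    b <- alt(v[s])
    setSite(off, "chr1", s,
            setNames(list(10L, 10L), paste0(b, c("_plus", "_minus"))))
  }
  # parental support below the calling bound but above the screen bound
  pb <- alt(v[parSite])
  setSite(p1, "chr1", parSite,
          setNames(list(17L, 17L, 2L, 1L),
                   c(paste0(v[parSite], c("_plus", "_minus")),
                     paste0(pb, c("_plus", "_minus")))))
  res <- callTrio(p1, p2, off, chars)
  expect_true(res$POLYMER[res$pos == polymerSite])
  expect_equal(res$status[res$pos == polymerSite], "REJECT")
  expect_true(res$MAPPING[res$pos == dupSite])
  expect_equal(res$status[res$pos == dupSite], "CONSENSUS_REQUIRED")
  expect_true(res$PARENTAL_SUPPORT[res$pos == parSite])
  expect_equal(res$status[res$pos == parSite], "REJECT")
  expect_equal(res$status[res$pos == cleanSite], "PASS")
})

test_that("consensus comparison assigns alleles and extracts mutations", {
  set.seed(21)
  a <- randSeq(2000)
  b <- ripscope:::mutateToIdentity(a, 0.95)
  # progeny identical to one allele
  expect_equal(consensusCompare(a, a, b)$allele, "A")
  expect_equal(nrow(consensusCompare(a, a, b)$mutations), 0L)
  # inter-allele differences are never reported as mutations
  resB <- consensusCompare(b, a, b)
  expect_equal(resB$allele, "B")
  expect_equal(nrow(resB$mutations), 0L)
  # planted C->T changes on allele A are recovered exactly
  v <- strsplit(a, "")[[1]]
  sites <- which(v == "C")[c(10, 50, 90, 130, 170)]
  v[sites] <- "T"
  res <- consensusCompare(paste(v, collapse = ""), a, b)
  expect_equal(res$allele, "A")
  expect_setequal(res$mutations$pos, sites)
  expect_true(all(res$mutations$ref == "C" & res$mutations$alt == "T"))
  # ambiguous assignment errors
  expect_error(consensusCompare(a, a, a), "ambiguous")
})

test_that("trio calling on simulated spores recovers planted mutations at
           shared loci and agrees with consensus mode", {
  par <- fixtureParents()
  cr <- fixtureCross(nTetrads = 1L)
  regions <- GenomicRanges::reduce(duplicateRegions(par) + 500L)
  obs <- emitObservables(cr, 1, seed = 6, regions = regions)
  g1 <- as.character(parentGenome(par, 1))
  g2 <- as.character(parentGenome(par, 2))
  set.seed(8)
  p1 <- ripscope:::emitPileupTable(g1, g1, 40, 0.002, regions)
  p2 <- ripscope:::emitPileupTable(g2, g1, 40, 0.002, regions)
  res <- callTrio(p1, p2, obs$pileup, parentGenome(par, 1))
  # no passing variant is heterozygous-like (haploid invariant)
  expect_false(any(res$hetLike[res$status != "REJECT"]))
  # recall over shared-presence (dispersed) duplicate families
  tr <- truthMutations(cr)
  tr <- tr[tr$spore == 1 &
             tr$family %in% c("hetA", "hetB", "hetC", "hetD",
                              "hetE", "hetF"), ]
  called <- paste(res$chrom, res$pos)[res$status != "REJECT"]
  expect_gte(mean(paste(tr$chrom, tr$pos) %in% called), 0.99)
  # consensus mode agrees exactly with pileup calling on one copy
  ann <- as.data.frame(duplicateAnnotation(par))
  het <- ann[ann$family == "hetA" & ann$copy == "A", ]
  prog <- substring(as.character(sporeGenome(cr, 1))[[het$seqnames]],
                    het$start, het$end)
  alleleA <- substring(g1[[het$seqnames]], het$start, het$end)
  alleleB <- substring(g1[[ann$seqnames[ann$family == "hetA" &
                                        ann$copy == "B"]]],
                       ann$start[ann$family == "hetA" & ann$copy == "B"],
                       ann$end[ann$family == "hetA" & ann$copy == "B"])
  cc <- consensusCompare(prog, alleleA, alleleB)
  expect_equal(cc$allele, "A")
  truthHetA <- tr[tr$family == "hetA" & tr$copy == "A", ]
  expect_setequal(cc$mutations$pos + het$start - 1L, truthHetA$pos)
})
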