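# End-to-end driver: simulate -> dupscan -> mutcall -> ripstats -> methmap,
# writing all artifacts plus a summary report and a reproducibility
# manifest.

#' Duplicate regions of a parental pair as a region set
#'
#' @param parents A [ParentalPair-class].
#' @param classes Restrict to chromatin classes (default all).
#' @param families Restrict to families (default all).
#' @param copies Restrict to copy labels (default all).
#' @return `GRanges` of the selected duplicate copies.
#' @export
duplicateRegions <- function(parents, classes = NULL, families = NULL,
                             copies = NULL) {
  ann <- duplicateAnnotation(parents)
  keep <- rep(TRUE, length(ann))
  if (!is.null(classes)) keep <- keep & ann$class %in% classes
  if (!is.null(families)) keep <- keep & ann$family %in% families
  if (!is.null(copies)) keep <- keep & ann$copy %in% copies
  ann[keep]
}

#' Parental methylation windows of a parental pair
#'
#' Duplicate copies annotated with their parental methylation level, for
#' use with [stratifyByParentalMethylation()].
#'
#' @param parents A [ParentalPair-class].
#' @return `GRanges` with a `level` metadata column.
#' @export
parentalMethWindows <- function(parents) {
  ann <- duplicateAnnotation(parents)
  out <- GRanges(seqnames(ann), IRanges(start(ann), end(ann)))
  mcols(out)$level <- ann$parentMeth
  out
}

## "wt" / "rid" / "rid+dim-2" -> canonical genotype vector
parseGenotype <- function(g) {
  if (length(g) == 1L && tolower(g) %in% c("wt", "wild-type", "wildtype", ""))
    return(character(0))
  normalizeGenotype(unlist(strsplit(g, "[+,;]")))
}

genotypeLabel <- function(genotype) {
  if (!length(genotype)) "wt" else paste(genotype, collapse = "+")
}

#' Run the full pipeline
#'
#' Executes the stages in order -- parental genome construction, one
#' simulated cross per requested genotype, duplicate scanning of the
#' parent-1 genome, trio mutation calling on the first wild-type spore,
#' rate statistics (per-genotype heterochromatic rates, reductions versus
#' wild type, methylation stratification) and parental methylome
#' comparisons -- writing every artifact under `outDir` together with a
#' summary and a manifest. A failing stage aborts with the stage named;
#' artifacts already written are retained.
#'
#' @param config Configuration from [loadConfig()] (or a list accepted by
#'   it).
#' @param seed Master seed (default: configuration seed).
#' @param outDir Output directory (default: configuration `out`).
#' @return Invisibly, the summary report list.
#' @export
runPipeline <- function(config = loadConfig(list()), seed = NULL,
                        outDir = NULL) {
  config <- if (is(config, "ripscopeConfig")) config else loadConfig(config)
  seed <- if (is.null(seed)) config$seed else seed
  outDir <- if (is.null(outDir)) config$out else outDir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  report <- list(seed = seed)

  sim <- config$simulate
  simCfg <- stage("simulate", defaultSimConfig(
    seed = seed, pEvent = sim$pEvent, pEventLinked = sim$pEventLinked,
    depth = sim$depth, errorRate = sim$errorRate, baseAT = sim$baseAT))
  parents <- stage("simulate", buildParentalGenomes(simCfg, seed))
  stage("simulate", {
    writeGenomeFasta(parents@genome1, file.path(outDir, "parent1.fasta"))
    writeGenomeFasta(parents@genome2, file.path(outDir, "parent2.fasta"))
    ann <- duplicateAnnotation(parents)
    writeBedTrack(ann, file.path(outDir, "duplicates.bed"),
                  names = paste(ann$family, ann$copy, sep = "_"))
  })
  genotypes <- lapply(unlist(sim$genotypes), parseGenotype)
  crosses <- list()
  for (g in genotypes) {
    lab <- genotypeLabel(g)
    crosses[[lab]] <- stage("simulate",
      simulateCross(parents, g, sim$nTetrads, seed))
    stage("simulate", writeVcfTable(
      truthMutations(crosses[[lab]])[, c("chrom", "pos", "ref", "alt",
                                         "spore", "family", "copy")],
      file.path(outDir, sprintf("truth_%s.vcf", lab)),
      contigs = simCfg@chromLengths))
  }

  ds <- config$dupscan
  pairs <- stage("dupscan", findDuplicatePairs(
    parents@genome1, minIdentity = ds$minIdentity,
    windowSize = ds$windowSize, k = ds$k))
  windows <- windowGenome(parents@genome1, ds$windowSize)
  dupAnn <- stage("dupscan", annotateDupWindows(windows, pairs))
  stage("dupscan", {
    utils::write.table(pairs, file.path(outDir, "dup_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    w <- dupAnn$windows
    writeBedTrack(w[w$dup], file.path(outDir, "dup_windows.bed"))
    writeBedTrack(w[!w$dup], file.path(outDir, "nondup_windows.bed"))
  })
  report$dupscan <- list(nPairs = nrow(pairs), dupSpan = dupAnn$dupSpan,
                         dupFraction = dupAnn$dupFraction)

  if ("wt" %in% names(crosses) && nSpores(crosses$wt) > 0) {
    mc <- config$mutcall
    trio <- stage("mutcall", {
      regions <- reduce(duplicateRegions(parents) + 1000L)
      obs <- emitObservables(crosses$wt, 1L, seed = seed, regions = regions)
      p1 <- emitPileupTable(asChromList(parents@genome1),
                            asChromList(parents@genome1),
                            simCfg@depth, simCfg@errorRate, regions)
      p2 <- emitPileupTable(asChromList(parents@genome2),
                            asChromList(parents@genome1),
                            simCfg@depth, simCfg@errorRate, regions)
      callTrio(p1, p2, obs$pileup, parents@genome1,
               homopolymerMin = mc$homopolymerMin,
               uniquenessK = mc$uniquenessK)
    })
    stage("mutcall", {
      pass <- trio[trio$status != "REJECT", , drop = FALSE]
      writeVcfTable(pass[, c("chrom", "pos", "ref", "alt", "status")],
                    file.path(outDir, "calls_spore1.vcf"),
                    contigs = simCfg@chromLengths)
      utils::write.table(trio, file.path(outDir, "calls_spore1_flags.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    })
    report$mutcall <- list(nCandidates = nrow(trio),
                           nPass = sum(trio$status == "PASS"),
                           nConsensus = sum(trio$status ==
                                              "CONSENSUS_REQUIRED"))
  }

  hetRegions <- duplicateRegions(parents,
                                 classes = c("constitutive", "transitional"))
  rates <- stage("ripstats", {
    vapply(crosses, function(cr)
      ripRate(truthMutations(cr), hetRegions, nSpores(cr)), numeric(1))
  })
  report$ripstats <- list(hetRatePerSampleMb = rates)
  if ("wt" %in% names(rates) && rates[["wt"]] > 0) {
    report$ripstats$reductionPct <-
      vapply(setdiff(names(rates), "wt"), function(g)
        reductionPct(rates[["wt"]], rates[[g]]), numeric(1))
  }
  if ("wt" %in% names(crosses)) {
    strat <- stage("ripstats", stratifyByParentalMethylation(
      truthMutations(crosses$wt), parentalMethWindows(parents), hetRegions,
      threshold = config$ripstats$methThreshold,
      nSamples = nSpores(crosses$wt)))
    utils::write.table(strat$table, file.path(outDir, "meth_strata.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$ripstats$highMethFraction <- strat$highFraction
  }

  mm <- config$methmap
  meth <- stage("methmap", {
    wt <- parentMethylome(parents, depth = simCfg@depth, seed = seed,
                          windowSize = mm$windowSize)
    ko <- parentMethylome(parents, "hda-1", depth = simCfg@depth,
                          seed = seed, windowSize = mm$windowSize)
    lens <- setNames(as.numeric(simCfg@chromLengths),
                     names(simCfg@chromLengths))
    wtW <- windowLevels(wt, mm$windowSize, lens)
    koW <- windowLevels(ko, mm$windowSize, lens)
    ch <- relativeChange(koW, wtW, mm$minWT)
    writeBisulfite(wt, file.path(outDir, "parent1_bisulfite_wt.tsv"))
    writeBisulfite(ko, file.path(outDir, "parent1_bisulfite_hda1.tsv"))
    utils::write.table(ch, file.path(outDir, "meth_change_hda1.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    hist <- changeHistogram(ch, mm$binWidth)
    utils::write.table(hist, file.path(outDir, "meth_change_hist.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    classifyLossProfile(ch)
  })
  report$methmap <- meth

  writeManifest(config, seed, file.path(outDir, "manifest.yaml"))
  saveRDSFree <- function(x, path) {   # plain-text summary, not a binary
    writeLines(yaml::as.yaml(x), path)
  }
  saveRDSFree(rapply(report, function(v)
    if (is.numeric(v)) unname(round(v, 6)) else v, how = "replace"),
    file.path(outDir, "summary.yaml"))
  invisible(report)
}
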