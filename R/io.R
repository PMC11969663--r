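# Format readers/writers (FASTA, BED, VCF, TSV dialects), configuration
# loading and the run manifest. Coordinates are 1-based inclusive inside
# the package, 1-based in VCF output and 0-based half-open in BED.

#' Write / read the pileup TSV dialect
#'
#' Columns: `chrom`, `pos` (1-based), `ref`, per-allele per-strand read
#' counts (`A_plus` .. `T_minus`) and a site quality score `qual`.
#'
#' @param pileup Pileup table.
#' @param path File path.
#' @return `readPileup` returns a `data.table`.
#' @export
writePileup <- function(pileup, path) {
  stopifnot(all(.PILEUP_COLS %in% names(pileup)))
  data.table::fwrite(as.data.frame(pileup)[, .PILEUP_COLS], path, sep = "\t")
  invisible(path)
}

#' @rdname writePileup
#' @export
readPileup <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  miss <- setdiff(.PILEUP_COLS, names(dt))
  if (length(miss))
    stop("malformed pileup file ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  dt[, `:=`(chrom = as.character(chrom), ref = as.character(ref))]
  dt
}

#' Write / read the bisulfite cytosine-count TSV dialect
#'
#' Columns: `chrom`, `pos` (1-based), `strand`, `meth`, `unmeth`.
#'
#' @param counts Count table.
#' @param path File path.
#' @return `readBisulfite` returns a `data.table`.
#' @export
writeBisulfite <- function(counts, path) {
  need <- c("chrom", "pos", "strand", "meth", "unmeth")
  stopifnot(all(need %in% names(counts)))
  data.table::fwrite(counts, path, sep = "\t")
  invisible(path)
}

#' @rdname writeBisulfite
#' @export
readBisulfite <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  need <- c("chrom", "pos", "strand", "meth", "unmeth")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("malformed bisulfite file ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  dt[, `:=`(chrom = as.character(chrom), strand = as.character(strand))]
  dt
}

#' Write / read a mutation table as VCF v4.2
#'
#' Positions are 1-based. Extra columns (`spore`, `family`, `copy`,
#' `class`) round-trip through INFO key=value pairs.
#'
#' @param mutations data.frame with `chrom`, `pos`, `ref`, `alt` and
#'   optional annotation columns.
#' @param path File path.
#' @param contigs Optional named vector of contig lengths for the header.
#' @return `readVcfTable` returns a data.frame.
#' @export
writeVcfTable <- function(mutations, path, contigs = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=ripscope"), con)
  if (!is.null(contigs))
    writeLines(sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                       as.integer(contigs)), con)
  extra <- setdiff(names(mutations), c("chrom", "pos", "ref", "alt"))
  for (e in extra)
    writeLines(sprintf(
      "##INFO=<ID=%s,Number=1,Type=String,Description=\"%s\">",
      toupper(e), e), con)
  writeLines(paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", sep = "\t"), con)
  if (nrow(mutations)) {
    info <- if (length(extra)) {
      apply(mutations[, extra, drop = FALSE], 1, function(r)
        paste(sprintf("%s=%s", toupper(extra), as.character(r)),
              collapse = ";"))
    } else rep(".", nrow(mutations))
    writeLines(paste(mutations$chrom, mutations$pos, ".", mutations$ref,
                     mutations$alt, ".", "PASS", info, sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname writeVcfTable
#' @export
readVcfTable <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  hdr <- lines[startsWith(lines, "#CHROM")]
  if (length(hdr) != 1L) stop("malformed VCF ", path, ": missing #CHROM line")
  if (!length(body))
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      stringsAsFactors = FALSE))
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 8L)
  if (length(bad))
    stop("malformed VCF ", path, ": line ",
         which(!startsWith(lines, "#"))[bad[1]], " has too few fields")
  out <- data.frame(chrom = vapply(parts, `[`, "", 1L),
                    pos = as.integer(vapply(parts, `[`, "", 2L)),
                    ref = vapply(parts, `[`, "", 4L),
                    alt = vapply(parts, `[`, "", 5L),
                    stringsAsFactors = FALSE)
  info <- vapply(parts, `[`, "", 8L)
  if (any(info != ".")) {
    kv <- strsplit(info, ";", fixed = TRUE)
    keys <- unique(sub("=.*", "", unlist(kv)))
    keys <- keys[keys != "."]
    for (k in keys) {
      vals <- vapply(kv, function(p) {
        hit <- p[startsWith(p, paste0(k, "="))]
        if (length(hit)) sub("^[^=]*=", "", hit[1]) else NA_character_
      }, character(1))
      col <- tolower(k)
      out[[col]] <- utils::type.convert(vals, as.is = TRUE)
    }
  }
  out
}

#' Write / read a BED track (0-based half-open)
#'
#' @param gr `GRanges` (1-based inclusive, converted on write) or, for
#'   reading, a path.
#' @param path File path.
#' @param names Optional feature names (4th column).
#' @return `readBedTrack` returns a `GRanges` (1-based inclusive).
#' @export
writeBedTrack <- function(gr, path, names = NULL) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr))
  if (!is.null(names)) df$name <- names
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeBedTrack
#' @export
readBedTrack <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  if (!length(lines)) return(GRanges())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop("malformed BED ", path, ": line ", bad[1], " has fewer than 3 fields")
  gr <- GRanges(vapply(parts, `[`, "", 1L),
                IRanges(as.integer(vapply(parts, `[`, "", 2L)) + 1L,
                        as.integer(vapply(parts, `[`, "", 3L))))
  if (all(lengths(parts) >= 4L))
    mcols(gr)$name <- vapply(parts, `[`, "", 4L)
  gr
}

#' Write genomes to FASTA
#'
#' @param genome `DNAStringSet` or named character vector.
#' @param path File path.
#' @export
writeGenomeFasta <- function(genome, path) {
  g <- if (is(genome, "DNAStringSet")) genome
       else DNAStringSet(asChromList(genome))
  writeXStringSet(g, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Configuration

.CONFIG_DEFAULTS <- function() list(
  seed = 1L,
  out = "ripscope-out",
  simulate = list(nTetrads = 50L, genotypes = list("wt"),
                  pEvent = 0.5, pEventLinked = 0.9, depth = 40,
                  errorRate = 0.002, baseAT = 0.5),
  dupscan = list(windowSize = 500L, minIdentity = 0.65, k = 11L),
  mutcall = list(minDepth = 5L, minQual = 30, homopolymerMin = 6L,
                 uniquenessK = 31L),
  ripstats = list(methThreshold = 0.10),
  methmap = list(windowSize = 100L, minWT = 0.1, binWidth = 0.05))

checkRange <- function(value, name, lo, hi) {
  if (!is.numeric(value) || length(value) != 1L || value < lo || value > hi)
    stop(sprintf("configuration value %s = %s out of range [%s, %s]",
                 name, as.character(value), lo, hi))
  value
}

#' Load and validate a run configuration (YAML)
#'
#' Unknown keys are rejected; missing keys are filled from the documented
#' defaults; out-of-range values raise distinct errors. The returned
#' object re-serialises to an equivalent configuration.
#'
#' @param path YAML file path, or a list already in memory.
#' @return Validated configuration list (class `ripscopeConfig`).
#' @export
loadConfig <- function(path) {
  cfg <- if (is.list(path)) path
  else {
    if (!file.exists(path)) stop("configuration file not found: ", path)
    out <- tryCatch(yaml::read_yaml(path),
                    error = function(e) stop("configuration parse error: ",
                                             conditionMessage(e)))
    if (is.null(out)) list() else out
  }
  defaults <- .CONFIG_DEFAULTS()
  bad <- setdiff(names(cfg), names(defaults))
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  for (sec in intersect(names(cfg), names(defaults))) {
    if (is.list(defaults[[sec]])) {
      badSub <- setdiff(names(cfg[[sec]]), names(defaults[[sec]]))
      if (length(badSub))
        stop("unknown configuration key(s): ",
             paste(paste0(sec, ".", badSub), collapse = ", "))
      defaults[[sec]][names(cfg[[sec]])] <- cfg[[sec]]
    } else defaults[[sec]] <- cfg[[sec]]
  }
  defaults$simulate$genotypes <- as.list(unlist(defaults$simulate$genotypes))
  checkRange(defaults$simulate$pEvent, "simulate.pEvent", 0, 1)
  checkRange(defaults$simulate$pEventLinked, "simulate.pEventLinked", 0, 1)
  checkRange(defaults$simulate$errorRate, "simulate.errorRate", 0, 0.499999)
  checkRange(defaults$simulate$depth, "simulate.depth", 1e-9, Inf)
  checkRange(defaults$simulate$nTetrads, "simulate.nTetrads", 0, Inf)
  checkRange(defaults$dupscan$minIdentity, "dupscan.minIdentity", 0, 1)
  checkRange(defaults$methmap$minWT, "methmap.minWT", 0, 1)
  structure(defaults, class = c("ripscopeConfig", "list"))
}

#' @rdname loadConfig
#' @param config Configuration list.
#' @param path Output YAML path.
#' @export
saveConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Write a run manifest (config, seed, package version)
#'
#' @param config Configuration list.
#' @param seed Seed used for the run.
#' @param path Output YAML path.
#' @export
writeManifest <- function(config, seed, path) {
  yaml::write_yaml(list(
    package = "ripscope",
    version = as.character(utils::packageVersion("ripscope")),
    seed = seed,
    config = unclass(config)), path)
  invisible(path)
}
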