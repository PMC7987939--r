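#' Create a pipeline run configuration
#'
#' All stage parameters have defaults; see [RunConfig] for their
#' meaning. Either FASTQ reads (screened and mapped internally) or a
#' pre-computed SAM per side (external aligner) may be supplied.
#'
#' @param referencePath reference FASTA.
#' @param leftFastq,rightFastq junction FASTQ per side ("" to skip).
#' @param leftSam,rightSam SAM per side ("" to use FASTQ + internal
#'   aligner).
#' @param constructName registered construct name.
#' @param outDir output directory.
#' @param k,maxEndMismatches,minGenomicLen,maxMismatches,mapqThreshold
#'   stage thresholds (see [RunConfig]).
#' @param windowHalfWidth,pseudocount logo parameters.
#' @param labels named character (`left`, `right`) library labels.
#' @param seed integer seed recorded in the summary.
#' @return a [RunConfig].
#' @export
runConfig <- function(referencePath, leftFastq = "", rightFastq = "",
                      leftSam = "", rightSam = "",
                      constructName = "pYT11",
                      outDir = tempfile("sbsites_run"),
                      k = 12L, maxEndMismatches = 1L,
                      minGenomicLen = 20L, maxMismatches = 2L,
                      mapqThreshold = 20L, windowHalfWidth = 10L,
                      pseudocount = 0.1,
                      labels = c(left = "left", right = "right"),
                      seed = 1L) {
  new("RunConfig", referencePath = referencePath, leftFastq = leftFastq,
      rightFastq = rightFastq, leftSam = leftSam, rightSam = rightSam,
      constructName = constructName, outDir = outDir, k = as.integer(k),
      maxEndMismatches = as.integer(maxEndMismatches),
      minGenomicLen = as.integer(minGenomicLen),
      maxMismatches = as.integer(maxMismatches),
      mapqThreshold = as.integer(mapqThreshold),
      windowHalfWidth = as.integer(windowHalfWidth),
      pseudocount = pseudocount, labels = labels, seed = as.integer(seed))
}

.config_slots <- c("referencePath", "leftFastq", "rightFastq", "leftSam",
                   "rightSam", "constructName", "outDir", "k",
                   "maxEndMismatches", "minGenomicLen", "maxMismatches",
                   "mapqThreshold", "windowHalfWidth", "pseudocount",
                   "labels", "seed")

#' Write a RunConfig to YAML
#' @param config a [RunConfig].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeRunConfig <- function(config, path) {
  x <- lapply(.config_slots, function(s) {
    v <- slot(config, s)
    if (!is.null(names(v))) as.list(v) else v
  })
  names(x) <- .config_slots
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a RunConfig from YAML
#' @param path file written by [writeRunConfig()].
#' @return a [RunConfig].
#' @export
readRunConfig <- function(path) {
  x <- yaml::read_yaml(path)
  x$labels <- unlist(x$labels)
  do.call(runConfig, x)
}

setMethod("show", "RunConfig", function(object) {
  cat("RunConfig\n")
  cat("  reference:", object@referencePath, "\n")
  cat("  construct:", object@constructName, "\n")
  cat(sprintf("  screen: maxEndMismatches %d, minGenomicLen %d\n",
              object@maxEndMismatches, object@minGenomicLen))
  cat(sprintf("  map: k %d, maxMismatches %d, mapqThreshold %d\n",
              object@k, object@maxMismatches, object@mapqThreshold))
  cat(sprintf("  logo: W %d, pseudocount %g\n",
              object@windowHalfWidth, object@pseudocount))
  cat("  outDir:", object@outDir, "\n")
})

.log_stage <- function(verbose, ...) {
  if (verbose) message("[sbsites] ", sprintf(...))
}

#' Run the full analysis pipeline
#'
#' Orchestrates screen -> map -> filter -> call -> dedupe -> tabulate
#' -> logos for the two junction libraries, writes a report bundle to
#' `config@outDir`, and asserts the stage-count ledger (every read is
#' accounted for at every boundary). Re-running with the same config
#' and inputs reproduces identical outputs.
#'
#' Bundle contents: per-library dinucleotide tables and site lists
#' (TSV/BED), non-TA site lists, per-library and combined non-TA PFMs
#' (TSV + SVG logos), side-bias and end-match summaries, and a
#' machine-readable `run_summary.json`.
#'
#' @param config a [RunConfig].
#' @param verbose log stage progress to stderr.
#' @return invisibly, a list: `tables` (per-library
#'   [DinucleotideTable]), `sites`, `nonTASites`, `pfms` (per-library
#'   and `combined`), `sideBias`, `endMatch`, `stats`, `paths`.
#' @export
runPipeline <- function(config, verbose = TRUE) {
  stopifnot(is(config, "RunConfig"))
  dir.create(config@outDir, showWarnings = FALSE, recursive = TRUE)
  genome <- readReference(config@referencePath)
  construct <- getConstruct(config@constructName)
  motifLen <- nchar(endMotif(construct))
  index <- NULL
  res <- list(tables = list(), sites = list(), nonTASites = list(),
              pfms = list(), sideBias = list(), endMatch = list(),
              stats = list(), paths = character())
  nonTAWindows <- list(left = character(), right = character())

  for (side in c("left", "right")) {
    label <- config@labels[[side]]
    fq <- slot(config, paste0(side, "Fastq"))
    sam <- slot(config, paste0(side, "Sam"))
    stats <- list()
    if (nzchar(sam)) {
      .log_stage(verbose, "%s: importing SAM %s", side, sam)
      aln <- importSam(sam, side, genome, config@mapqThreshold)
      stats$reads <- nrow(aln)
    } else if (nzchar(fq)) {
      .log_stage(verbose, "%s: screening %s", side, fq)
      scr <- screenAndTrim(fq, construct, side, config@maxEndMismatches,
                           config@minGenomicLen)
      stats$screen <- scr$stats
      stats$reads <- scr$stats[["total"]]
      stopifnot(scr$stats[["matched"]] + scr$stats[["tooShort"]] +
                  scr$stats[["rejected"]] == scr$stats[["total"]])
      if (is.null(index)) {
        .log_stage(verbose, "building k-mer index (k = %d)", config@k)
        index <- buildKmerIndex(genome, config@k)
      }
      .log_stage(verbose, "%s: mapping %d fragments", side,
                 nrow(scr$trimmed))
      aln <- mapFragments(index, genome, scr$trimmed,
                          config@maxMismatches)
    } else {
      next  # side not provided
    }
    stats$mapStatus <- table(aln$status)
    flt <- filterAlignments(aln, config@minGenomicLen)
    stats$filter <- flt$stats
    stopifnot(flt$stats[["kept"]] +
                flt$stats[["droppedUnmapped"]] +
                flt$stats[["droppedAmbiguous"]] +
                flt$stats[["droppedShort"]] == flt$stats[["input"]])
    cs <- callSites(flt$kept, genome)
    dd <- dedupeSites(cs$sites)
    stats$called <- length(cs$sites)
    stats$discardedOutOfBounds <- cs$discarded
    stats$duplicates <- dd$duplicateCount
    stats$uniqueSites <- length(dd$sites)
    stopifnot(stats$uniqueSites ==
                flt$stats[["kept"]] - cs$discarded - dd$duplicateCount)
    sites <- dd$sites
    tab <- dinucleotideTable(sites, label)
    res$tables[[side]] <- tab
    res$sites[[side]] <- sites
    res$stats[[side]] <- stats

    sp <- file.path(config@outDir, paste0("sites_", side, ".tsv"))
    bp <- file.path(config@outDir, paste0("sites_", side, ".bed"))
    writeSites(sites, sp, bp)
    res$paths <- c(res$paths, sp, bp)

    nonTA <- sites[!mcols(sites)$isTA]
    res$nonTASites[[side]] <- nonTA
    if (length(nonTA)) {
      fl <- extractFlanks(genome, nonTA, config@windowHalfWidth)
      nonTAWindows[[side]] <- fl$windows
      if (length(fl$windows)) {
        pfm <- buildPFM(fl$windows, config@pseudocount)
        res$pfms[[side]] <- pfm
        res$sideBias[[side]] <- sideBias(pfm, motifLen)
        res$endMatch[[side]] <-
          endMatchScore(pfm, deriveEndMotif(construct, side))
        pp <- file.path(config@outDir, paste0("pfm_nonTA_", side, ".tsv"))
        lp <- file.path(config@outDir, paste0("logo_nonTA_", side, ".svg"))
        writePFM(pfm, pp)
        writeLogoSVG(pfm, lp, paste("non-TA", side, "library"))
        res$paths <- c(res$paths, pp, lp)
      }
    }
    .log_stage(verbose, "%s: %d unique sites, %d non-TA", side,
               length(sites), length(nonTA))
  }

  if (length(nonTAWindows$left) || length(nonTAWindows$right)) {
    pfm <- combineSides(nonTAWindows$left, nonTAWindows$right,
                        config@pseudocount)
    res$pfms$combined <- pfm
    res$endMatch$combined <- endMatchScore(pfm, endMotif(construct))
    pp <- file.path(config@outDir, "pfm_nonTA_combined.tsv")
    lp <- file.path(config@outDir, "logo_nonTA_combined.svg")
    writePFM(pfm, pp)
    writeLogoSVG(pfm, lp, "non-TA combined (right side reverse-complemented)")
    res$paths <- c(res$paths, pp, lp)
  }

  rp <- renderReport(res$tables, res$pfms, res$sideBias, res$endMatch,
                     file.path(config@outDir, "report.txt"))
  res$paths <- c(res$paths, rp)
  summary <- list(
    parameters = list(construct = config@constructName, k = config@k,
                      maxEndMismatches = config@maxEndMismatches,
                      minGenomicLen = config@minGenomicLen,
                      maxMismatches = config@maxMismatches,
                      mapqThreshold = config@mapqThreshold,
                      W = config@windowHalfWidth,
                      pseudocount = config@pseudocount,
                      seed = config@seed),
    stages = res$stats,
    nonTAProportion = lapply(res$tables, nonTAProportion),
    sideBias = res$sideBias,
    endMatch = res$endMatch)
  sj <- file.path(config@outDir, "run_summary.json")
  jsonlite::write_json(summary, sj, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  res$paths <- c(res$paths, sj)
  invisible(res)
}

#' Render the text report of a run
#'
#' Dinucleotide rows in the fixed reporting order, totals and non-TA
#' proportions at 3 decimals, logo/PFM summaries and side-bias and
#' end-match numbers. When a library has no non-TA sites the logo
#' block is skipped with a note.
#'
#' @param tables named list of [DinucleotideTable] per library.
#' @param pfms named list of [PositionFrequencyMatrix] (may be empty).
#' @param sideBiasValues,endMatchValues named numeric lists.
#' @param path output text file.
#' @return `path`, invisibly.
#' @export
renderReport <- function(tables, pfms = list(), sideBiasValues = list(),
                         endMatchValues = list(),
                         path = "report.txt") {
  out <- c("Integration site report",
           "coordinates in site TSVs are 1-based inclusive", "")
  for (nm in names(tables)) {
    t <- tables[[nm]]
    out <- c(out, sprintf("Library: %s", t@label),
             sprintf("  %-2s %10s", "dn", "count"),
             vapply(DINUCLEOTIDE_ORDER, function(d)
               sprintf("  %-2s %10s", d,
                       format(t@counts[[d]], big.mark = ",")),
               character(1)),
             sprintf("  total        %10s",
                     format(totalSites(t), big.mark = ",")),
             sprintf("  non-TA       %10s",
                     format(nonTACount(t), big.mark = ",")),
             sprintf("  non-TA %%     %10s",
                     if (is.na(nonTAProportion(t))) "NA"
                     else sprintf("%.3f%%", nonTAProportion(t))),
             "")
  }
  if (!length(pfms)) {
    out <- c(out, "No non-TA sites: consensus logo step skipped.", "")
  } else {
    for (nm in names(pfms)) {
      p <- pfms[[nm]]
      out <- c(out, sprintf("PFM [%s]: n = %d, consensus %s", nm,
                            nSequences(p),
                            paste(pfmConsensus(p), collapse = "")))
      if (!is.null(sideBiasValues[[nm]]))
        out <- c(out, sprintf("  side bias (distal - proximal IC): %+.3f bits",
                              sideBiasValues[[nm]]))
      if (!is.null(endMatchValues[[nm]]))
        out <- c(out, sprintf("  end-motif match of consensus: %.2f",
                              endMatchValues[[nm]]))
      out <- c(out, "")
    }
  }
  writeLines(out, path)
  invisible(path)
}
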