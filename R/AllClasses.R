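#' @import methods
#' @importFrom stats rbinom rpois runif setNames
#' @importFrom utils read.delim write.table
NULL

.DNA_BASES <- c("A", "C", "G", "T")

#' Dinucleotide reporting order
#'
#' The 16 dinucleotides in the order used by all count tables
#' (TA first, then the remaining 15; CA and TG are counted separately,
#' i.e. no palindromic/strand collapsing).
#'
#' @format Character vector of length 16.
#' @export
DINUCLEOTIDE_ORDER <- c("TA", "CA", "TG", "TT", "AA", "GA", "TC", "AG",
                        "CT", "GG", "CC", "AT", "GT", "AC", "GC", "CG")

#' TransposonConstruct class
#'
#' Models a transposon construct's two end sequences as they appear at
#' the 5' of a junction read (transposon portion before the genomic
#' fragment) together with the short end motif, in logo orientation,
#' used for consensus comparison. The motif in logo orientation is the
#' reverse complement of the outermost bases of the inverted repeat
#' written 5'->3' outward, so the canonical IR terminus CAGT... gives
#' motif ACTG, and mutating the second and third outer bases AG->GA
#' gives ATCG.
#'
#' @slot name construct name (unique within a registry).
#' @slot leftEnd DNA string; transposon portion of a left-junction read.
#' @slot rightEnd DNA string; likewise for right-junction reads.
#' @slot endMotif DNA string (default length 4), logo orientation.
#' @slot motifMutant named logical of length 2 (`left`, `right`);
#'   whether that end's motif region has been mutated.
#'
#' @export
setClass("TransposonConstruct",
  representation(name = "character", leftEnd = "character",
                 rightEnd = "character", endMotif = "character",
                 motifMutant = "logical"))

setValidity("TransposonConstruct", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "name must be a single non-empty string")
  for (s in c("leftEnd", "rightEnd")) {
    x <- slot(object, s)
    if (length(x) != 1L || !nzchar(x))
      msg <- c(msg, sprintf("%s must be a non-empty DNA string", s))
    else if (!.is_dna(x, allow_n = FALSE))
      msg <- c(msg, sprintf("%s contains characters outside {A,C,G,T}", s))
  }
  if (length(object@endMotif) != 1L || nchar(object@endMotif) < 2L)
    msg <- c(msg, "endMotif must have length >= 2")
  else if (!.is_dna(object@endMotif, allow_n = FALSE))
    msg <- c(msg, "endMotif contains characters outside {A,C,G,T}")
  if (length(object@motifMutant) != 2L ||
      !identical(names(object@motifMutant), c("left", "right")))
    msg <- c(msg, "motifMutant must be logical(2) named left, right")
  if (length(msg)) msg else TRUE
})

#' SimulationParams class
#'
#' Parameters of the synthetic-data generator. Defaults describe the
#' emulated study conditions: a mostly-TA-targeting transposon with a
#' small aberrant fraction (`pNonTA = 0.014`, the non-TA integration
#' frequency reported for large-scale screens), aberrant distal flanks
#' resembling the transposon end motif (`motifMatchProb = 0.8` per
#' base), Q30-level substitution error, and LM-PCR duplicate reads.
#'
#' @slot genomeLength integer vector, length of each chromosome (bp).
#' @slot gc GC fraction of the i.i.d. genome.
#' @slot nEvents number of integration events.
#' @slot pNonTA per-event probability of an aberrant (non-TA) event.
#' @slot motifMatchProb per-base probability that the aberrant distal
#'   flank matches the end motif.
#' @slot readLength junction read length (transposon end + genomic
#'   fragment); must exceed end length + 20.
#' @slot errorRate per-base substitution sequencing error rate.
#' @slot dupLambda duplicates per read follow 1 + Poisson(dupLambda).
#' @slot excludeCpG if TRUE, CG is excluded from the non-TA
#'   dinucleotide draw.
#' @slot bothSidesNonTA if TRUE, aberrant events carry non-TA
#'   dinucleotides at both junctions (robustness testing only; the
#'   default model has exactly one non-TA junction per aberrant event).
#' @slot distinctSites if TRUE (default) integration positions are
#'   sampled without replacement so every event is a distinct site.
#' @slot seed integer seed; mandatory, drives all randomness.
#'
#' @export
setClass("SimulationParams",
  representation(genomeLength = "numeric", gc = "numeric",
                 nEvents = "integer", pNonTA = "numeric",
                 motifMatchProb = "numeric", readLength = "integer",
                 errorRate = "numeric", dupLambda = "numeric",
                 excludeCpG = "logical", bothSidesNonTA = "logical",
                 distinctSites = "logical", seed = "integer"))

setValidity("SimulationParams", function(object) {
  msg <- character()
  if (length(object@genomeLength) < 1L || any(object@genomeLength < 1000))
    msg <- c(msg, "genomeLength: every chromosome must be >= 1 kb")
  for (s in c("gc", "pNonTA", "motifMatchProb", "errorRate")) {
    x <- slot(object, s)
    if (length(x) != 1L || is.na(x) || x < 0 || x > 1)
      msg <- c(msg, sprintf("%s must be a probability in [0,1]", s))
  }
  if (length(object@nEvents) != 1L || object@nEvents < 1L)
    msg <- c(msg, "nEvents must be >= 1")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed is mandatory")
  if (object@dupLambda < 0) msg <- c(msg, "dupLambda must be >= 0")
  if (length(msg)) msg else TRUE
})

#' KmerIndex class
#'
#' Exact k-mer -> plus-strand position index over a reference genome,
#' used to seed the internal aligner. Minus-strand hits are found by
#' looking up the reverse complement of query k-mers, so only plus
#' strand positions are stored.
#'
#' @slot k k-mer size (8..16).
#' @slot index data.table keyed by kmer with columns chrom, pos
#'   (0-based plus-strand position of the k-mer's first base).
#' @slot seqlengths named integer vector of chromosome lengths.
#'
#' @export
setClass("KmerIndex",
  representation(k = "integer", index = "ANY", seqlengths = "integer"))

#' DinucleotideTable class
#'
#' A 16-way histogram of target dinucleotides for one library, in the
#' fixed reporting order of [DINUCLEOTIDE_ORDER], with derived totals
#' and non-TA proportion.
#'
#' @slot label library label.
#' @slot counts named integer vector of length 16 (all 16 dinucleotides
#'   reported explicitly, including zero counts).
#'
#' @export
setClass("DinucleotideTable",
  representation(label = "character", counts = "integer"))

setValidity("DinucleotideTable", function(object) {
  msg <- character()
  if (!identical(names(object@counts), DINUCLEOTIDE_ORDER))
    msg <- c(msg, "counts must be named by DINUCLEOTIDE_ORDER")
  if (any(is.na(object@counts)) || any(object@counts < 0L))
    msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' PositionFrequencyMatrix class
#'
#' Per-position base counts over aligned flanking windows of length
#' 2W+2 (positions -W..-1, D1, D2, +1..+W in sequenced orientation;
#' D1 D2 is the target dinucleotide, negative offsets are the
#' junction-proximal / sequenced side, positive offsets the distal
#' side). Frequencies carry a pseudocount; the information-content
#' profile and consensus are derived by accessors.
#'
#' @slot counts 4 x P integer matrix, rows A,C,G,T, columns labelled
#'   by window position.
#' @slot n number of windows tallied.
#' @slot pseudocount pseudocount added per base when converting counts
#'   to frequencies.
#'
#' @export
setClass("PositionFrequencyMatrix",
  representation(counts = "matrix", n = "integer", pseudocount = "numeric"))

setValidity("PositionFrequencyMatrix", function(object) {
  msg <- character()
  if (!identical(rownames(object@counts), .DNA_BASES))
    msg <- c(msg, "counts rows must be A,C,G,T")
  if (ncol(object@counts) < 2L || ncol(object@counts) %% 2L != 0L)
    msg <- c(msg, "window length must be even (2W+2)")
  if (object@pseudocount < 0) msg <- c(msg, "pseudocount must be >= 0")
  if (length(msg)) msg else TRUE
})

#' RunConfig class
#'
#' Configuration of a full pipeline run: input paths, construct, and
#' every stage parameter. All stage parameters have defaults; a config
#' round-trips losslessly through YAML ([writeRunConfig()] /
#' [readRunConfig()]).
#'
#' @slot referencePath reference genome FASTA.
#' @slot leftFastq,rightFastq junction read FASTQ per sequenced side
#'   (may be empty strings if a SAM path is supplied instead).
#' @slot leftSam,rightSam optional pre-computed alignments in SAM
#'   (external-aligner entry point); when set, screening/mapping for
#'   that side is skipped.
#' @slot constructName name of the construct in the registry.
#' @slot outDir output directory.
#' @slot k k-mer size of the internal aligner index.
#' @slot maxEndMismatches substitutions tolerated in the transposon-end
#'   prefix during screening.
#' @slot minGenomicLen minimum genomic fragment length kept.
#' @slot maxMismatches mismatch allowance of the internal aligner.
#' @slot mapqThreshold SAM records under this MAPQ become `ambiguous`.
#' @slot windowHalfWidth logo window half-width W.
#' @slot pseudocount PFM pseudocount.
#' @slot labels named character (left, right): library labels.
#' @slot seed integer seed recorded in the run summary.
#'
#' @export
setClass("RunConfig",
  representation(referencePath = "character", leftFastq = "character",
                 rightFastq = "character", leftSam = "character",
                 rightSam = "character", constructName = "character",
                 outDir = "character", k = "integer",
                 maxEndMismatches = "integer", minGenomicLen = "integer",
                 maxMismatches = "integer", mapqThreshold = "integer",
                 windowHalfWidth = "integer", pseudocount = "numeric",
                 labels = "character", seed = "integer"))
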