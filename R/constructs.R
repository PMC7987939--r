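## Package-level construct registry (populated with presets on load).
.registry <- new.env(parent = emptyenv())

.default_motif_len <- 4L

## Placeholder 20-base synthetic end sequences for simulation: the last
## .default_motif_len bases are the end motif in read/logo orientation
## (the transposon portion of a junction read ends with the motif, then
## the target dinucleotide, then genomic sequence). The remaining bases
## are arbitrary fixed anchors; the real IR/DR sequences are
## configuration, not constants.
.LEFT_ANCHOR  <- "TGTCATGACAATTCCA"
.RIGHT_ANCHOR <- "GTGGTGATCCTAAGCA"

#' Create and register a transposon construct
#'
#' Stores a [TransposonConstruct] in the package registry under a
#' unique name. If `endMotif` is omitted it is derived from the left
#' end sequence (its last `motifLen` bases, i.e. the transposon bases
#' adjacent to the junction in read orientation).
#'
#' @param name unique construct name.
#' @param leftEnd,rightEnd end sequences as they appear at the 5' of a
#'   junction read, before the genomic fragment.
#' @param endMotif motif (logo orientation) used for consensus
#'   comparison; default derived from `leftEnd`.
#' @param motifMutant named logical(2) (`left`, `right`).
#' @param motifLen motif length used when deriving from the end.
#' @return the registered [TransposonConstruct], invisibly.
#' @export
registerConstruct <- function(name, leftEnd, rightEnd, endMotif = NULL,
                              motifMutant = c(left = FALSE, right = FALSE),
                              motifLen = .default_motif_len) {
  if (exists(name, envir = .registry, inherits = FALSE))
    stop("registerConstruct: construct already registered: ", name)
  leftEnd <- toupper(leftEnd); rightEnd <- toupper(rightEnd)
  if (is.null(endMotif))
    endMotif <- substr(leftEnd, nchar(leftEnd) - motifLen + 1L, nchar(leftEnd))
  obj <- new("TransposonConstruct", name = name, leftEnd = leftEnd,
             rightEnd = rightEnd, endMotif = toupper(endMotif),
             motifMutant = motifMutant)
  validObject(obj)
  assign(name, obj, envir = .registry)
  invisible(obj)
}

#' Look up a construct by name
#' @param name construct name.
#' @return [TransposonConstruct].
#' @export
getConstruct <- function(name) {
  if (!exists(name, envir = .registry, inherits = FALSE))
    stop("getConstruct: unknown construct: ", name,
         " (see listConstructs())")
  get(name, envir = .registry, inherits = FALSE)
}

#' List registered construct names
#' @return character vector.
#' @export
listConstructs <- function() sort(ls(envir = .registry))

#' Reset the construct registry to the shipped presets
#'
#' Presets: `pYT11` (classical ends, motif ACTG), `pYT21` (left end
#' mutated, motif ATCG), `pYT22` (right end mutated only; motif ACTG,
#' matching its native left end), `pYT23` (both ends mutated, motif
#' ATCG) and `pYT53` (A>T transversion at the second outer nucleotide
#' of the left end; motif ACAG under this package's orientation
#' mapping, overridable).
#'
#' @return invisibly, the registered names.
#' @export
resetConstructRegistry <- function() {
  rm(list = ls(envir = .registry), envir = .registry)
  native <- "ACTG"   # revcomp of outer IR terminus 5'-CAGT...
  mutant <- "ATCG"   # outer AG -> GA at positions 2-3
  ty53   <- "ACAG"   # outer A > T at position 2
  registerConstruct("pYT11", paste0(.LEFT_ANCHOR, native),
                    paste0(.RIGHT_ANCHOR, native))
  registerConstruct("pYT21", paste0(.LEFT_ANCHOR, mutant),
                    paste0(.RIGHT_ANCHOR, native),
                    motifMutant = c(left = TRUE, right = FALSE))
  registerConstruct("pYT22", paste0(.LEFT_ANCHOR, native),
                    paste0(.RIGHT_ANCHOR, mutant),
                    motifMutant = c(left = FALSE, right = TRUE))
  registerConstruct("pYT23", paste0(.LEFT_ANCHOR, mutant),
                    paste0(.RIGHT_ANCHOR, mutant),
                    motifMutant = c(left = TRUE, right = TRUE))
  registerConstruct("pYT53", paste0(.LEFT_ANCHOR, ty53),
                    paste0(.RIGHT_ANCHOR, native),
                    motifMutant = c(left = TRUE, right = FALSE))
  invisible(listConstructs())
}

#' @describeIn TransposonConstruct-accessors construct name
#' @export
constructName <- function(x) x@name
#' Accessors for TransposonConstruct
#'
#' @param x a [TransposonConstruct].
#' @param side `"left"` or `"right"`.
#' @name TransposonConstruct-accessors
NULL
#' @describeIn TransposonConstruct-accessors left end sequence
#' @export
leftEnd <- function(x) x@leftEnd
#' @describeIn TransposonConstruct-accessors right end sequence
#' @export
rightEnd <- function(x) x@rightEnd
#' @describeIn TransposonConstruct-accessors comparison motif (logo
#'   orientation)
#' @export
endMotif <- function(x) x@endMotif
#' @describeIn TransposonConstruct-accessors end sequence of one side
#' @export
endSequence <- function(x, side = c("left", "right")) {
  side <- match.arg(side)
  if (side == "left") x@leftEnd else x@rightEnd
}

#' Derive the end motif from an end sequence
#'
#' The motif is a deterministic function of the end sequence and the
#' declared motif length: its last `motifLen` bases (the transposon
#' bases adjacent to the junction, read orientation). Re-deriving is
#' idempotent.
#'
#' @param x a [TransposonConstruct].
#' @param side which end to derive from.
#' @param motifLen motif length.
#' @return DNA string.
#' @export
deriveEndMotif <- function(x, side = c("left", "right"),
                           motifLen = nchar(x@endMotif)) {
  side <- match.arg(side)
  e <- endSequence(x, side)
  substr(e, nchar(e) - motifLen + 1L, nchar(e))
}

#' Mutate a construct end within the motif region
#'
#' Applies a single-base substitution at `position` (1-based within the
#' motif, i.e. within the junction-adjacent bases of the chosen end)
#' consistently to the end sequence and, for the left end, to the
#' construct motif. Returns a new construct; the original is unchanged.
#' Position 1 of the motif corresponds to the outermost-but-adjacent
#' region whose terminal bases are critical for transposition, so a
#' mutation there triggers a warning (not an error).
#'
#' @param x a [TransposonConstruct].
#' @param side `"left"` or `"right"`.
#' @param position 1-based position within the motif.
#' @param newBase one of A, C, G, T.
#' @param name name of the derived construct (not auto-registered);
#'   default `<name>_mut`.
#' @return a new [TransposonConstruct].
#' @export
mutateEnd <- function(x, side = c("left", "right"), position, newBase,
                      name = paste0(x@name, "_mut")) {
  side <- match.arg(side)
  L <- nchar(x@endMotif)
  if (!is.numeric(position) || length(position) != 1L ||
      position < 1 || position > L)
    stop("mutateEnd: position must be within 1..", L, " (motif coordinates)")
  newBase <- toupper(newBase)
  if (!newBase %in% .DNA_BASES)
    stop("mutateEnd: newBase must be one of A, C, G, T")
  if (position == 1)
    warning("mutateEnd: position 1 borders the terminal bases critical ",
            "for transposition; typically kept unchanged")
  e <- endSequence(x, side)
  epos <- nchar(e) - L + as.integer(position)
  substr(e, epos, epos) <- newBase
  y <- x
  y@name <- name
  if (side == "left") {
    y@leftEnd <- e
    y@endMotif <- deriveEndMotif(y, "left", L)
  } else {
    y@rightEnd <- e
  }
  y@motifMutant[[side]] <- TRUE
  validObject(y)
  y
}

#' Write the construct registry to a YAML file
#' @param path output file.
#' @param names constructs to write (default: all registered).
#' @return `path`, invisibly.
#' @export
writeConstructRegistry <- function(path, names = listConstructs()) {
  recs <- lapply(names, function(nm) {
    x <- getConstruct(nm)
    list(name = x@name, left_end = x@leftEnd, right_end = x@rightEnd,
         end_motif = x@endMotif,
         motif_mutant = as.list(x@motifMutant))
  })
  yaml::write_yaml(recs, path)
  invisible(path)
}

#' Read constructs from a YAML registry file
#'
#' Registers every record; duplicate names (in the file or against the
#' current registry) are an error.
#'
#' @param path registry file written by [writeConstructRegistry()].
#' @return invisibly, the names registered.
#' @export
readConstructRegistry <- function(path) {
  recs <- yaml::read_yaml(path)
  nms <- vapply(recs, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("readConstructRegistry: duplicate construct name in file")
  for (r in recs)
    registerConstruct(r$name, r$left_end, r$right_end, r$end_motif,
                      motifMutant = c(left = isTRUE(r$motif_mutant$left),
                                      right = isTRUE(r$motif_mutant$right)))
  invisible(nms)
}

setMethod("show", "TransposonConstruct", function(object) {
  cat("TransposonConstruct", object@name, "\n")
  cat("  left end : 5'-", object@leftEnd, "-3'",
      if (object@motifMutant[["left"]]) " (mutated)" else "", "\n", sep = "")
  cat("  right end: 5'-", object@rightEnd, "-3'",
      if (object@motifMutant[["right"]]) " (mutated)" else "", "\n", sep = "")
  cat("  end motif: 5'-", object@endMotif, "-3'\n", sep = "")
})
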