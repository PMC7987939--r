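## prefix mismatch counts of many reads against one end sequence
.prefix_mismatches <- function(seqs, end) {
  n <- length(seqs)
  if (!n) return(integer())
  elen <- nchar(end)
  mm <- rep(NA_integer_, n)
  long <- nchar(seqs) >= elen
  if (any(long)) {
    pre <- substr(seqs[long], 1L, elen)
    endCh <- strsplit(end, "")[[1]]
    M <- matrix(unlist(strsplit(pre, ""), use.names = FALSE), nrow = elen)
    mm[long] <- as.integer(colSums(M != endCh))
  }
  mm  # NA = read shorter than the end: cannot match
}

#' Screen junction reads for a transposon end and trim it
#'
#' A read is kept iff its 5' prefix matches the requested side's end
#' sequence with at most `maxEndMismatches` substitutions (the match is
#' prefix-anchored: LM-PCR amplicons are primer-anchored, so the end is
#' expected at the very start of the read). Kept reads are trimmed at
#' the exact end length; trimmed fragments shorter than
#' `minGenomicLen` are counted separately.
#'
#' @param reads FASTQ path, or a named character vector /
#'   [Biostrings::DNAStringSet] of read sequences.
#' @param construct a [TransposonConstruct].
#' @param side `"left"` or `"right"`.
#' @param maxEndMismatches substitutions tolerated in the end prefix
#'   (default 1 over the 20-base end anchor: tolerates Q30-level error
#'   without admitting spurious matches).
#' @param minGenomicLen minimum genomic fragment length (default 20;
#'   shorter fragments cannot map uniquely).
#' @return list with `trimmed` (data.frame: `id`, `side`, `fragment`,
#'   `mismatches`) and `stats` (named integer: `total`, `matched`,
#'   `tooShort`, `rejected`; `matched + tooShort + rejected == total`).
#' @export
screenAndTrim <- function(reads, construct, side = c("left", "right"),
                          maxEndMismatches = 1L, minGenomicLen = 20L) {
  side <- match.arg(side)
  stopifnot(maxEndMismatches >= 0L)
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- readDNAStringSet(reads, format = "fastq")
  ids <- names(reads)
  seqs <- toupper(as.character(reads))
  if (is.null(ids)) ids <- paste0("read", seq_along(seqs))
  end <- endSequence(construct, side)
  if (!nzchar(end)) stop("screenAndTrim: no ", side, " end defined")
  mm <- .prefix_mismatches(seqs, end)
  matched <- !is.na(mm) & mm <= maxEndMismatches
  frag <- substr(seqs[matched], nchar(end) + 1L, nchar(seqs[matched]))
  longEnough <- nchar(frag) >= minGenomicLen
  trimmed <- data.frame(id = ids[matched][longEnough],
                        side = rep(side, sum(longEnough)),
                        fragment = frag[longEnough],
                        mismatches = mm[matched][longEnough],
                        stringsAsFactors = FALSE)
  stats <- c(total = length(seqs), matched = nrow(trimmed),
             tooShort = sum(matched) - nrow(trimmed),
             rejected = sum(!matched))
  list(trimmed = trimmed, stats = stats)
}

#' Write trimmed fragments to TSV
#' @param trimmed data.frame from [screenAndTrim()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTrimmed <- function(trimmed, path) {
  write.table(trimmed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
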