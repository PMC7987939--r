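#' Call integration sites from filtered alignments
#'
#' The target dinucleotide of a junction fragment is its first two
#' bases in read orientation, taken from the mapped reference (robust
#' to sequencing error; set `useReadDinuc = TRUE` to read it off the
#' fragment instead, for diagnostics). For a plus-strand alignment that
#' is `genome[start0, start0+2)`; for a minus-strand alignment the
#' reverse complement of the last two reference bases of the fragment.
#' `dinucStart0` is always the plus-strand coordinate of the pair.
#' Dinucleotides are reported in the sequenced orientation with no
#' palindromic collapsing (CA and TG are distinct). Sites whose
#' dinucleotide window would leave the contig are discarded and
#' counted.
#'
#' @param alignments unique alignments (the `kept` element of
#'   [filterAlignments()]).
#' @param genome named [Biostrings::DNAStringSet] or named character.
#' @param useReadDinuc take the dinucleotide from the read fragment
#'   (requires a `fragment` column) instead of the reference.
#' @param fragments optional named character of fragments (read id ->
#'   sequence) when `useReadDinuc = TRUE`.
#' @return list with `sites` (a [GenomicRanges::GRanges]: 1-based
#'   2-bp ranges on the dinucleotide, strand = alignment strand, mcols
#'   `side`, `dinucleotide`, `isTA`, `readId`) and `discarded`
#'   (out-of-bounds count).
#' @export
callSites <- function(alignments, genome, useReadDinuc = FALSE,
                      fragments = NULL) {
  a <- alignments[alignments$status == "unique", , drop = FALSE]
  gchr <- .genome_chr(genome)
  lens <- nchar(gchr)
  if (!nrow(a)) {
    return(list(sites = GRanges(), discarded = 0L))
  }
  plus <- a$strand == "+"
  dstart <- ifelse(plus, a$start0, a$start0 + a$len - 2L)
  ok <- dstart >= 0L & dstart + 2L <= lens[a$chrom]
  discarded <- sum(!ok)
  a <- a[ok, , drop = FALSE]; dstart <- dstart[ok]; plus <- plus[ok]
  if (useReadDinuc) {
    if (is.null(fragments))
      stop("callSites: useReadDinuc requires fragments")
    dinuc <- toupper(substr(fragments[a$id], 1L, 2L))
  } else {
    dinuc <- unname(substring(gchr[a$chrom], dstart + 1L, dstart + 2L))
    dinuc[!plus] <- .revcomp_chr(dinuc[!plus])
  }
  dinuc <- unname(dinuc)
  gr <- GRanges(a$chrom, IRanges(dstart + 1L, width = 2L),
                strand = a$strand)
  mcols(gr)$side <- a$side
  mcols(gr)$dinucleotide <- dinuc
  mcols(gr)$isTA <- dinuc == "TA"
  mcols(gr)$readId <- a$id
  list(sites = gr, discarded = discarded)
}

#' Collapse PCR-duplicate sites
#'
#' Position-level deduplication: one site is kept per
#' (chrom, dinucleotide position, strand, side); the dropped count is
#' returned. Idempotent. Two independent events at identical
#' coordinates on the same strand and side are indistinguishable from
#' duplicates and counted once. Set `byPosition = FALSE` to count
#' reads instead (no collapsing).
#'
#' @param sites [GenomicRanges::GRanges] from [callSites()].
#' @param byPosition collapse by position (default) or keep all reads.
#' @return list with `sites` (deduplicated GRanges) and
#'   `duplicateCount`.
#' @export
dedupeSites <- function(sites, byPosition = TRUE) {
  if (!byPosition || !length(sites))
    return(list(sites = sites, duplicateCount = 0L))
  key <- paste(as.character(seqnames(sites)), start(sites),
               as.character(strand(sites)), mcols(sites)$side, sep = "\r")
  keep <- !duplicated(key)
  list(sites = sites[keep], duplicateCount = sum(!keep))
}

#' Tabulate target dinucleotides for one library
#'
#' Exact 16-way histogram in the fixed reporting order
#' ([DINUCLEOTIDE_ORDER]); zero counts are reported explicitly.
#'
#' @param sites [GenomicRanges::GRanges] from [callSites()], or a
#'   character vector of dinucleotides.
#' @param label library label.
#' @return a [DinucleotideTable].
#' @export
dinucleotideTable <- function(sites, label = "library") {
  d <- if (is(sites, "GRanges")) mcols(sites)$dinucleotide
       else as.character(sites)
  counts <- table(factor(d, levels = DINUCLEOTIDE_ORDER))
  new("DinucleotideTable", label = label,
      counts = setNames(as.integer(counts), DINUCLEOTIDE_ORDER))
}

#' Build a DinucleotideTable from printed counts
#'
#' For entering published per-dinucleotide counts directly (e.g. to
#' check a table's internal arithmetic). Missing dinucleotides default
#' to zero.
#'
#' @param counts named numeric vector (names are dinucleotides).
#' @param label library label.
#' @return a [DinucleotideTable].
#' @export
dinucleotideTableFromCounts <- function(counts, label = "library") {
  bad <- setdiff(names(counts), DINUCLEOTIDE_ORDER)
  if (length(bad))
    stop("dinucleotideTableFromCounts: not dinucleotides: ",
         paste(bad, collapse = ", "))
  full <- setNames(integer(16L), DINUCLEOTIDE_ORDER)
  full[names(counts)] <- as.integer(counts)
  new("DinucleotideTable", label = label, counts = full)
}

#' @describeIn DinucleotideTable-accessors per-dinucleotide counts
#' @export
dinucCounts <- function(x) x@counts
#' Accessors for DinucleotideTable
#' @param x a [DinucleotideTable].
#' @param digits decimals for the percentage (default 3, matching the
#'   conventional reporting precision).
#' @name DinucleotideTable-accessors
NULL
#' @describeIn DinucleotideTable-accessors total number of sites
#' @export
totalSites <- function(x) sum(x@counts)
#' @describeIn DinucleotideTable-accessors number of non-TA sites
#' @export
nonTACount <- function(x) sum(x@counts) - x@counts[["TA"]]
#' @describeIn DinucleotideTable-accessors non-TA percentage,
#'   `100 * (total - TA) / total`; `NA` for an empty table
#' @export
nonTAProportion <- function(x, digits = 3L) {
  tot <- totalSites(x)
  if (tot == 0L) return(NA_real_)
  round(100 * nonTACount(x) / tot, digits)
}

setMethod("show", "DinucleotideTable", function(object) {
  cat("DinucleotideTable:", object@label, "\n")
  for (d in DINUCLEOTIDE_ORDER)
    cat(sprintf("  %s  %s\n", d,
                format(object@counts[[d]], big.mark = ",")))
  cat(sprintf("  total %s, non-TA %s (%s%%)\n",
              format(totalSites(object), big.mark = ","),
              format(nonTACount(object), big.mark = ","),
              format(nonTAProportion(object), nsmall = 3)))
})

#' Convert a DinucleotideTable to a data.frame
#' @param x a [DinucleotideTable].
#' @return data.frame with `dinucleotide` and `count` columns in
#'   reporting order.
#' @export
dinucTableAsDataFrame <- function(x) {
  data.frame(dinucleotide = DINUCLEOTIDE_ORDER,
             count = unname(x@counts[DINUCLEOTIDE_ORDER]))
}

#' Write sites as TSV (1-based) and BED6 (0-based half-open)
#'
#' The TSV reports 1-based inclusive coordinates (stated in the
#' header); the BED is 0-based half-open with the dinucleotide as name.
#'
#' @param sites [GenomicRanges::GRanges] of sites.
#' @param tsvPath,bedPath output paths (either may be NULL to skip).
#' @return invisibly, a character vector of paths written.
#' @export
writeSites <- function(sites, tsvPath = NULL, bedPath = NULL) {
  out <- character()
  df <- data.frame(chrom = as.character(seqnames(sites)),
                   pos_1based = start(sites),
                   strand = as.character(strand(sites)),
                   side = mcols(sites)$side,
                   dinucleotide = mcols(sites)$dinucleotide,
                   is_TA = mcols(sites)$isTA)
  if (!is.null(tsvPath)) {
    con <- file(tsvPath, "w")
    writeLines("# integration sites; pos_1based = 1-based inclusive position of the target dinucleotide's first base", con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    out <- c(out, tsvPath)
  }
  if (!is.null(bedPath)) {
    bed <- data.frame(df$chrom, df$pos_1based - 1L, df$pos_1based + 1L,
                      df$dinucleotide, 0L, df$strand)
    write.table(bed, bedPath, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    out <- c(out, bedPath)
  }
  invisible(out)
}
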