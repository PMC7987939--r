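#' @import data.table
NULL

#' Build an exact k-mer index over a reference genome
#'
#' Maps every plus-strand k-mer to its 0-based positions. Minus-strand
#' queries are served by looking up the reverse complement of the query
#' k-mer, so the index itself stores plus-strand positions only.
#' Deterministic: repeated builds are identical.
#'
#' @param genome named [Biostrings::DNAStringSet] or named character.
#' @param k k-mer size, 8..16 (default 12) and no larger than the
#'   shortest contig.
#' @return a [KmerIndex].
#' @export
buildKmerIndex <- function(genome, k = 12L) {
  k <- as.integer(k)
  if (k < 8L || k > 16L) stop("buildKmerIndex: k must be in 8..16")
  gchr <- .genome_chr(genome)
  lens <- nchar(gchr)
  if (k > min(lens))
    stop("buildKmerIndex: k exceeds the shortest contig length")
  tabs <- lapply(names(gchr), function(cn) {
    n <- lens[[cn]]
    pos <- 0:(n - k)
    data.table(kmer = substring(gchr[[cn]], pos + 1L, pos + k),
               chrom = cn, pos = pos)
  })
  idx <- rbindlist(tabs)
  setkey(idx, kmer)
  new("KmerIndex", k = k, index = idx,
      seqlengths = setNames(as.integer(lens), names(gchr)))
}

setMethod("show", "KmerIndex", function(object) {
  cat(sprintf("KmerIndex: k = %d over %d contig(s), %s positions\n",
              object@k, length(object@seqlengths),
              format(nrow(object@index), big.mark = ",")))
})

## seed starts: all non-overlapping k-mer tiles plus the terminal k-mer.
## Guarantees the best hit is found whenever mismatches < floor(len/k).
.seed_offsets <- function(len, k) {
  off <- seq.int(0L, len - k, by = k)
  unique(c(off, len - k))
}

#' Map trimmed genomic fragments with the internal aligner
#'
#' Seed-and-extend: candidate loci are seeded from exact k-mer hits of
#' the fragment's non-overlapping k-mer tiles (and terminal k-mer) on
#' both strands, then each candidate is scored by Hamming comparison
#' over the full fragment. The best alignment is the one with fewest
#' mismatches `<= maxMismatches`; a tie between two or more loci gives
#' status `ambiguous`, no qualifying locus gives `unmapped` (neither
#' carries coordinates). The search is exhaustive-equivalent whenever
#' the true mismatch count is below `floor(len/k)`.
#'
#' @param index a [KmerIndex].
#' @param genome the genome the index was built on.
#' @param fragments character vector of fragments (named by read id),
#'   or the `trimmed` data.frame of [screenAndTrim()].
#' @param maxMismatches mismatch allowance (default 2).
#' @param side optional side label carried through.
#' @return data.frame: `id`, `side`, `status`
#'   (unique/ambiguous/unmapped), `chrom`, `start0` (0-based leftmost
#'   reference base on the plus strand), `strand` (+ if the fragment
#'   matches the plus strand, - if its reverse complement does),
#'   `mismatches`, `len`. Coordinates are `NA` unless status is
#'   `unique`.
#' @export
mapFragments <- function(index, genome, fragments, maxMismatches = 2L,
                         side = NA_character_) {
  stopifnot(is(index, "KmerIndex"))
  if (is.data.frame(fragments)) {
    if (all(is.na(side)) && "side" %in% names(fragments))
      side <- fragments$side
    fragments <- setNames(fragments$fragment, fragments$id)
  }
  gchr <- .genome_chr(genome)
  k <- index@k
  n <- length(fragments)
  ids <- names(fragments)
  if (is.null(ids)) ids <- paste0("frag", seq_len(n))
  empty <- data.frame(id = character(), side = character(),
                      status = character(), chrom = character(),
                      start0 = integer(), strand = character(),
                      mismatches = integer(), len = integer(),
                      stringsAsFactors = FALSE)
  if (!n) return(empty)
  frags <- toupper(unname(fragments))
  lens <- nchar(frags)
  if (any(lens < k))
    stop("mapFragments: fragment shorter than k = ", k)
  rcfrags <- .revcomp_chr(frags)

  qparts <- lapply(seq_len(n), function(i) {
    off <- .seed_offsets(lens[i], k)
    data.table(fid = i,
               kmer = c(substring(frags[i], off + 1L, off + k),
                        substring(rcfrags[i], off + 1L, off + k)),
               off = c(off, off),
               strand = rep(c("+", "-"), each = length(off)))
  })
  q <- rbindlist(qparts)
  idx <- index@index
  cand <- idx[q, on = "kmer", allow.cartesian = TRUE, nomatch = NULL]
  status <- rep("unmapped", n)
  best <- data.frame(chrom = NA_character_, start0 = NA_integer_,
                     strand = NA_character_, mismatches = NA_integer_)
  best <- best[rep(1L, n), ]
  if (nrow(cand)) {
    cand[, start0 := pos - off]
    cand[, len := lens[fid]]
    cand <- unique(cand[, .(fid, chrom, start0, strand, len)])
    cand <- cand[start0 >= 0L & start0 + len <= index@seqlengths[chrom]]
  }
  if (nrow(cand)) {
    cand[, region := substring(gchr[chrom], start0 + 1L, start0 + len)]
    cand[, query := fifelse(strand == "+", frags[fid], rcfrags[fid])]
    cand[, mm := 0L]
    neq <- which(cand$region != cand$query)
    if (length(neq))
      cand$mm[neq] <- .hamming(cand$region[neq], cand$query[neq])
    cand <- cand[mm <= maxMismatches]
  }
  if (nrow(cand)) {
    cand[, bestmm := min(mm), by = fid]
    top <- cand[mm == bestmm]
    nb <- top[, .N, by = fid]
    uniq <- nb[N == 1L, fid]
    amb <- nb[N > 1L, fid]
    status[amb] <- "ambiguous"
    status[uniq] <- "unique"
    u <- top[fid %in% uniq]
    best$chrom[u$fid] <- u$chrom
    best$start0[u$fid] <- u$start0
    best$strand[u$fid] <- u$strand
    best$mismatches[u$fid] <- u$mm
  }
  data.frame(id = ids, side = side, status = status, chrom = best$chrom,
             start0 = best$start0, strand = best$strand,
             mismatches = best$mismatches, len = lens,
             stringsAsFactors = FALSE)
}

#' Map a single fragment
#'
#' Convenience wrapper around [mapFragments()].
#'
#' @inheritParams mapFragments
#' @param fragment one DNA string.
#' @return one-row data.frame (see [mapFragments()]).
#' @export
mapFragment <- function(index, genome, fragment, maxMismatches = 2L) {
  mapFragments(index, genome, setNames(fragment, "frag1"), maxMismatches)
}

#' Import alignments from a SAM file
#'
#' Reads a SAM file (via Rsamtools), keeping primary records only.
#' Records flagged unmapped become status `unmapped`; mapped records
#' with MAPQ below `mapqThreshold` become `ambiguous`; the rest are
#' `unique`. SAM 1-based POS is converted to the internal 0-based
#' start. Mismatch counts are taken from the NM tag when present. The
#' SAM header must declare the contigs (`@SQ`), and every aligned
#' contig must exist in the supplied reference with a consistent
#' length.
#'
#' @param path SAM file.
#' @param side side label ("left"/"right") carried through.
#' @param reference named [Biostrings::DNAStringSet] or named
#'   character, used to validate the header.
#' @param mapqThreshold MAPQ threshold (default 20).
#' @return data.frame in the layout of [mapFragments()].
#' @export
importSam <- function(path, side, reference, mapqThreshold = 20L) {
  if (!file.exists(path)) stop("importSam: no such file: ", path)
  bam <- tryCatch(
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE),
    error = function(e)
      stop("importSam: cannot parse SAM (missing/invalid header?): ",
           conditionMessage(e), call. = FALSE))
  on.exit(unlink(bam))
  targets <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (!length(targets))
    stop("importSam: SAM has no @SQ header lines")
  refLens <- setNames(nchar(.genome_chr(reference)),
                      names(.genome_chr(reference)))
  bad <- setdiff(names(targets), names(refLens))
  if (length(bad))
    stop("importSam: contig(s) absent from the reference: ",
         paste(bad, collapse = ", "))
  if (any(targets != refLens[names(targets)]))
    stop("importSam: contig length mismatch with the reference")
  flags <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "qwidth"),
    tag = "NM", flag = flags)
  r <- Rsamtools::scanBam(bam, param = p)[[1]]
  unmapped <- bitwAnd(r$flag, 4L) > 0L
  status <- ifelse(unmapped, "unmapped",
                   ifelse(r$mapq < mapqThreshold, "ambiguous", "unique"))
  nm <- r$tag$NM
  if (is.null(nm)) nm <- rep(NA_integer_, length(r$flag))
  keep <- status == "unique"
  data.frame(id = r$qname, side = side, status = status,
             chrom = ifelse(keep, as.character(r$rname), NA_character_),
             start0 = ifelse(keep, r$pos - 1L, NA_integer_),
             strand = ifelse(keep,
                             ifelse(bitwAnd(r$flag, 16L) > 0L, "-", "+"),
                             NA_character_),
             mismatches = ifelse(keep, ifelse(is.na(nm), 0L, nm),
                                 NA_integer_),
             len = ifelse(is.na(r$qwidth), 0L, r$qwidth),
             stringsAsFactors = FALSE)
}

#' Filter alignments before site calling
#'
#' Keeps unique alignments (when `requireUnique`) of fragments at
#' least `minFragmentLen` long; every dropped record is counted by
#' reason, and kept + dropped equals the input.
#'
#' @param alignments data.frame from [mapFragments()] or
#'   [importSam()].
#' @param minFragmentLen minimum fragment length (default 20).
#' @param requireUnique drop ambiguous alignments (default TRUE).
#' @return list with `kept` (data.frame) and `stats` (named integer:
#'   `input`, `kept`, `droppedUnmapped`, `droppedAmbiguous`,
#'   `droppedShort`).
#' @export
filterAlignments <- function(alignments, minFragmentLen = 20L,
                             requireUnique = TRUE) {
  a <- alignments
  dropU <- a$status == "unmapped"
  dropA <- !dropU & requireUnique & a$status == "ambiguous"
  dropS <- !dropU & !dropA & a$len < minFragmentLen
  keep <- !(dropU | dropA | dropS)
  list(kept = a[keep, , drop = FALSE],
       stats = c(input = nrow(a), kept = sum(keep),
                 droppedUnmapped = sum(dropU),
                 droppedAmbiguous = sum(dropA),
                 droppedShort = sum(dropS)))
}

#' Export alignments as BED6
#'
#' 0-based half-open intervals of the aligned fragments (unique
#' alignments only), score = mismatch count.
#'
#' @param alignments data.frame of alignments.
#' @param path output BED file.
#' @return `path`, invisibly.
#' @export
writeAlignmentsBed <- function(alignments, path) {
  a <- alignments[alignments$status == "unique", , drop = FALSE]
  bed <- data.frame(a$chrom, a$start0, a$start0 + a$len, a$id,
                    a$mismatches, a$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
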