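#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet
#'   writeXStringSet reverseComplement BStringSet matchPattern
#'   neditStartingAt consensusMatrix
#' @importFrom GenomicRanges GRanges seqnames start end strand
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- metadata metadata<-
NULL

.is_dna <- function(x, allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  all(grepl(pat, x))
}

## Fast vectorised reverse complement on plain character vectors.
.revcomp_chr <- function(x) {
  if (!length(x)) return(character())
  out <- vapply(strsplit(chartr("ACGTN", "TGCAN", x), "", fixed = TRUE),
                function(ch) paste(rev(ch), collapse = ""), character(1))
  unname(out)
}

#' Reverse complement of DNA strings
#'
#' Vectorised over a character vector. Alphabet is restricted to
#' A, C, G, T, N (N maps to N); anything else is an error.
#'
#' @param seq character vector of DNA strings.
#' @return character vector of reverse complements.
#' @examples
#' revcomp(c("ACTG", "TA"))
#' @export
revcomp <- function(seq) {
  seq <- toupper(as.character(seq))
  if (!.is_dna(seq)) stop("revcomp: sequences must be over {A,C,G,T,N}")
  .revcomp_chr(seq)
}

#' Read a reference genome from FASTA
#'
#' Wraps [Biostrings::readDNAStringSet()]: every record is captured,
#' sequences are uppercased, names are the first whitespace-delimited
#' token of the header. Duplicate or empty names, empty sequences and
#' characters outside {A,C,G,T,N} are rejected.
#'
#' @param path FASTA file.
#' @return named [Biostrings::DNAStringSet] (the reference genome).
#' @export
readReference <- function(path) {
  if (!file.exists(path)) stop("readReference: no such file: ", path)
  g <- tryCatch(readDNAStringSet(path, format = "fasta"),
                error = function(e)
                  stop("readReference: malformed FASTA (", path, "): ",
                       conditionMessage(e), call. = FALSE))
  names(g) <- sub("\\s.*$", "", names(g))
  if (any(!nzchar(names(g)))) stop("readReference: empty sequence name")
  if (anyDuplicated(names(g)))
    stop("readReference: duplicate sequence name(s): ",
         paste(unique(names(g)[duplicated(names(g))]), collapse = ", "))
  if (any(lengths(g) == 0L)) stop("readReference: empty sequence(s)")
  chr <- toupper(as.character(g))
  if (!.is_dna(chr))
    stop("readReference: characters outside {A,C,G,T,N}")
  DNAStringSet(chr)
}

#' Write a reference genome to FASTA
#'
#' Multi-line FASTA wrapped at 60 columns; round-trips with
#' [readReference()].
#'
#' @param genome named [Biostrings::DNAStringSet] or named character.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeReference <- function(genome, path) {
  if (is.character(genome)) genome <- DNAStringSet(genome)
  writeXStringSet(genome, path, format = "fasta", width = 60L)
  invisible(path)
}

## Named character view of a genome; inner loops use plain strings.
.genome_chr <- function(genome) {
  if (is.character(genome)) {
    if (is.null(names(genome))) stop("genome must be named")
    return(toupper(genome))
  }
  setNames(as.character(genome), names(genome))
}

#' Fetch the sequence of a genomic interval
#'
#' Coordinates are 0-based half-open. For `strand == "-"` the reverse
#' complement of the plus-strand substring is returned, so
#' `fetchInterval(g, c, s, e, "+")` and `fetchInterval(g, c, s, e, "-")`
#' are always reverse complements of each other.
#'
#' @param genome named [Biostrings::DNAStringSet] or named character.
#' @param chrom chromosome name.
#' @param start0 0-based inclusive start.
#' @param end0 0-based exclusive end.
#' @param strand "+" or "-".
#' @return DNA string (character scalar).
#' @export
fetchInterval <- function(genome, chrom, start0, end0, strand = "+") {
  g <- .genome_chr(genome)
  if (!chrom %in% names(g)) stop("fetchInterval: unknown chromosome ", chrom)
  len <- nchar(g[[chrom]])
  if (is.na(start0) || is.na(end0) || start0 < 0 || end0 > len ||
      start0 >= end0)
    stop(sprintf("fetchInterval: interval [%s, %s) out of bounds on %s (length %d)",
                 format(start0), format(end0), chrom, len))
  s <- substr(g[[chrom]], start0 + 1L, end0)
  if (strand == "-") s <- .revcomp_chr(s)
  s
}

#' Fetch sequences for a GRanges
#'
#' Strand-aware batch retrieval (1-based GRanges coordinates, `*`
#' treated as `+`).
#'
#' @param genome named [Biostrings::DNAStringSet] or named character.
#' @param gr [GenomicRanges::GRanges].
#' @return character vector of sequences, one per range.
#' @export
fetchRanges <- function(genome, gr) {
  g <- .genome_chr(genome)
  chrom <- as.character(seqnames(gr))
  bad <- setdiff(unique(chrom), names(g))
  if (length(bad)) stop("fetchRanges: unknown chromosome(s): ",
                        paste(bad, collapse = ", "))
  st <- start(gr); en <- end(gr)
  len <- nchar(g)[chrom]
  if (any(st < 1L) || any(en > len))
    stop("fetchRanges: range out of bounds on ",
         paste(unique(chrom[st < 1L | en > len]), collapse = ", "))
  out <- substring(g[chrom], st, en)
  neg <- as.character(strand(gr)) == "-"
  if (any(neg)) out[neg] <- .revcomp_chr(out[neg])
  unname(out)
}

## Hamming distance between equal-length strings (vectorised pairs).
.hamming <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  out <- integer(n)
  neq <- which(a != b)
  for (i in neq) out[i] <- sum(charToRaw(a[i]) != charToRaw(b[i]))
  out
}
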