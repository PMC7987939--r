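#' Extract strand-normalized flanking windows around target
#' dinucleotides
#'
#' For each site the window covers positions -W..-1, D1, D2, +1..+W in
#' the sequenced orientation (length 2W+2): for a plus-strand site the
#' plus-strand bases `genome[dinucStart-W, dinucStart+2+W)`, for a
#' minus-strand site the reverse complement of the same interval, so
#' D1 D2 always equals the reported dinucleotide. Negative offsets are
#' the junction-proximal (sequenced/primer) side, positive offsets the
#' distal side. Windows that would leave the contig, or that contain
#' N, are excluded and counted.
#'
#' @param genome named [Biostrings::DNAStringSet] or named character.
#' @param sites [GenomicRanges::GRanges] from [callSites()].
#' @param W window half-width (default 10: wide enough for a 4-base
#'   motif plus context).
#' @return list with `windows` (character vector), `excludedBounds`
#'   and `excludedN` counts.
#' @export
extractFlanks <- function(genome, sites, W = 10L) {
  W <- as.integer(W)
  if (W < 1L) stop("extractFlanks: W must be >= 1")
  if (!length(sites))
    return(list(windows = character(), excludedBounds = 0L,
                excludedN = 0L))
  gchr <- .genome_chr(genome)
  lens <- nchar(gchr)
  chrom <- as.character(seqnames(sites))
  d0 <- start(sites) - 1L
  from <- d0 - W
  to <- d0 + 1L + W
  ok <- from >= 0L & to + 1L <= lens[chrom]
  win <- unname(substring(gchr[chrom[ok]], from[ok] + 1L, to[ok] + 1L))
  neg <- as.character(strand(sites))[ok] == "-"
  win[neg] <- .revcomp_chr(win[neg])
  hasN <- grepl("N", win, fixed = TRUE)
  list(windows = win[!hasN], excludedBounds = sum(!ok),
       excludedN = sum(hasN))
}

#' Build a position frequency matrix from aligned windows
#'
#' Tallies base counts per position over equal-length windows
#' (alphabet A,C,G,T). Frequencies are smoothed with a pseudocount:
#' `(count + pc) / (n + 4 pc)`. The default pseudocount 0.1 stabilizes
#' consensus calls at small site counts (tens of sequences).
#'
#' @param windows character vector (or DNAStringSet) of equal-length
#'   windows over A,C,G,T.
#' @param pseudocount pseudocount per base (default 0.1).
#' @return a [PositionFrequencyMatrix].
#' @export
buildPFM <- function(windows, pseudocount = 0.1) {
  windows <- toupper(as.character(windows))
  if (!length(windows)) stop("buildPFM: no windows")
  if (length(unique(nchar(windows))) != 1L)
    stop("buildPFM: windows differ in length")
  if (!.is_dna(windows, allow_n = FALSE))
    stop("buildPFM: windows must be over {A,C,G,T}")
  cm <- consensusMatrix(DNAStringSet(windows))
  counts <- matrix(0L, nrow = 4L, ncol = nchar(windows[1]),
                   dimnames = list(.DNA_BASES, NULL))
  present <- intersect(rownames(cm), .DNA_BASES)
  counts[present, ] <- cm[present, , drop = FALSE]
  P <- ncol(counts)
  W <- (P - 2L) %/% 2L
  colnames(counts) <- c(if (W > 0L) paste0(-W:-1), "D1", "D2",
                        if (W > 0L) paste0("+", 1:W))
  new("PositionFrequencyMatrix", counts = counts,
      n = length(windows), pseudocount = pseudocount)
}

#' @describeIn PositionFrequencyMatrix-accessors number of windows
#' @export
nSequences <- function(x) x@n
#' Accessors for PositionFrequencyMatrix
#' @param x a [PositionFrequencyMatrix].
#' @name PositionFrequencyMatrix-accessors
NULL
#' @describeIn PositionFrequencyMatrix-accessors raw base counts
#'   (4 x P matrix)
#' @export
pfmCounts <- function(x) x@counts
#' @describeIn PositionFrequencyMatrix-accessors pseudocount-smoothed
#'   per-position base frequencies (each column sums to 1)
#' @export
baseFrequencies <- function(x) {
  f <- (x@counts + x@pseudocount) / (x@n + 4 * x@pseudocount)
  f
}
#' @describeIn PositionFrequencyMatrix-accessors consensus string:
#'   argmax base per position, `N` on ties
#' @export
pfmConsensus <- function(x) {
  apply(x@counts, 2L, function(col) {
    m <- which(col == max(col))
    if (length(m) > 1L) "N" else .DNA_BASES[m]
  })
}

#' Per-position information content of a PFM
#'
#' `IC_j = sum_b f_bj log2(f_bj / q_b)` with `0 log 0 = 0`, using the
#' pseudocount-smoothed frequencies. Under the default uniform
#' background `q = 1/4` the IC lies in `[0, 2]` bits. A genome
#' composition background may be supplied instead (must sum to 1).
#' No small-sample correction is applied by default;
#' `smallSampleCorrection = TRUE` subtracts the Schneider-style
#' expected bias `3 / (2 ln 2 n)` (floored at 0).
#'
#' @param x a [PositionFrequencyMatrix].
#' @param background length-4 base background (A,C,G,T order).
#' @param smallSampleCorrection apply the Schneider-style correction.
#' @return named numeric vector of bits per window position.
#' @export
informationContent <- function(x, background = rep(0.25, 4),
                               smallSampleCorrection = FALSE) {
  if (length(background) != 4L || abs(sum(background) - 1) > 1e-9)
    stop("informationContent: background must be 4 values summing to 1")
  f <- baseFrequencies(x)
  term <- f * log2(f / background)
  term[f == 0] <- 0
  ic <- colSums(term)
  if (smallSampleCorrection)
    ic <- pmax(0, ic - 3 / (2 * log(2) * x@n))
  ic
}

#' Combine left- and right-library windows into one PFM
#'
#' Right-library windows are reverse complemented (mapping their
#' -W..-1 side onto +1..+W) and pooled with the left-library windows,
#' aligning both libraries on a common orientation so the pooled
#' matrix has `n = n_left + n_right`. Either list may be empty.
#'
#' @param leftWindows,rightWindows character vectors of equal-length
#'   windows (`windows` element of [extractFlanks()]).
#' @param pseudocount PFM pseudocount.
#' @return a [PositionFrequencyMatrix].
#' @export
combineSides <- function(leftWindows, rightWindows, pseudocount = 0.1) {
  leftWindows <- as.character(leftWindows)
  rightWindows <- as.character(rightWindows)
  if (length(leftWindows) && length(rightWindows) &&
      nchar(leftWindows[1]) != nchar(rightWindows[1]))
    stop("combineSides: window lengths differ between sides")
  pooled <- c(leftWindows, .revcomp_chr(rightWindows))
  buildPFM(pooled, pseudocount)
}

## window-position label -> column index; offset 1 = first distal base,
## 0 = D2, -1 = D1, -2 = last proximal base, ...
.offset_col <- function(offset, W) {
  col <- W + 2L + as.integer(offset)
  if (any(col < 1L) || any(col > 2L * W + 2L))
    stop("offset outside the window")
  col
}

#' Fraction of motif positions matched by the PFM consensus
#'
#' Compares the consensus base at `offset .. offset+L-1` (default
#' offset +1: the first L distal positions, immediately 3' of the
#' target dinucleotide) with the end motif. Ties (consensus `N`) count
#' as mismatches. Use `offset = -1` to start the comparison at D1
#' (including the target-site-duplication positions in the alignment).
#'
#' @param x a [PositionFrequencyMatrix].
#' @param motif DNA string.
#' @param offset window offset of the motif's first base (default 1).
#' @return fraction in `[0, 1]`.
#' @export
endMatchScore <- function(x, motif, offset = 1L) {
  motif <- toupper(motif)
  L <- nchar(motif)
  P <- ncol(x@counts)
  W <- (P - 2L) %/% 2L
  cols <- tryCatch(.offset_col(seq.int(offset, length.out = L), W),
                   error = function(e)
                     stop("endMatchScore: motif overruns the window",
                          call. = FALSE))
  cons <- pfmConsensus(x)[cols]
  mean(cons == strsplit(motif, "")[[1]])
}

#' Distal-minus-proximal information content (junction-side bias)
#'
#' Mean information content over the distal positions +1..+L minus the
#' mean over the proximal positions -L..-1. Positive values indicate
#' that the consensus signal sits on the side opposite the sequencing
#' primer.
#'
#' @param x a [PositionFrequencyMatrix].
#' @param L number of flanking positions compared per side (default 4,
#'   the end-motif length).
#' @param background IC background (see [informationContent()]).
#' @return numeric scalar (bits).
#' @export
sideBias <- function(x, L = 4L, background = rep(0.25, 4)) {
  P <- ncol(x@counts)
  W <- (P - 2L) %/% 2L
  if (L > W) stop("sideBias: L must be <= W")
  ic <- informationContent(x, background)
  mean(ic[.offset_col(1:L, W)]) - mean(ic[.offset_col(-(L + 1L):-2L, W)])
}

setMethod("show", "PositionFrequencyMatrix", function(object) {
  P <- ncol(object@counts)
  cat(sprintf("PositionFrequencyMatrix: %d sequences, window %d (W = %d)\n",
              object@n, P, (P - 2L) %/% 2L))
  cat("  consensus:", paste(pfmConsensus(object), collapse = ""), "\n")
  ic <- informationContent(object)
  cat(sprintf("  IC: total %.2f bits, max %.2f at %s\n",
              sum(ic), max(ic), colnames(object@counts)[which.max(ic)]))
})

#' Write a PFM (counts, frequencies, IC, consensus) as TSV
#'
#' Positions as rows (-W..-1, D1, D2, +1..+W) with per-base counts,
#' smoothed frequencies, information content and the consensus base.
#'
#' @param x a [PositionFrequencyMatrix].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePFM <- function(x, path) {
  f <- baseFrequencies(x)
  df <- data.frame(position = colnames(x@counts),
                   t(x@counts),
                   t(round(f, 6)),
                   ic_bits = round(informationContent(x), 6),
                   consensus = pfmConsensus(x))
  names(df)[2:5] <- paste0("count_", .DNA_BASES)
  names(df)[6:9] <- paste0("freq_", .DNA_BASES)
  con <- file(path, "w")
  writeLines(sprintf("# PFM over %d sequences, pseudocount %g", x@n,
                     x@pseudocount), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Render a minimal sequence-logo SVG
#'
#' Letters stacked per position, heights proportional to
#' `IC_j * f_bj` (bits), tallest on top; D1/D2 positions are marked.
#' This is a plain self-contained SVG, good enough to eyeball the
#' consensus and its side bias.
#'
#' @param x a [PositionFrequencyMatrix].
#' @param path output `.svg` file.
#' @param title optional title text.
#' @return `path`, invisibly.
#' @export
writeLogoSVG <- function(x, path, title = "") {
  f <- baseFrequencies(x)
  ic <- informationContent(x)
  P <- ncol(f)
  W <- (P - 2L) %/% 2L
  colw <- 24; h <- 160; base <- 140; scale <- (base - 20) / 2
  cols <- c(A = "#109648", C = "#255C99", G = "#F7B32B", T = "#D62839")
  svg <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
                   P * colw + 60, h + 30),
           sprintf('<text x="5" y="14" font-size="12">%s</text>', title))
  for (j in seq_len(P)) {
    x0 <- 40 + (j - 1) * colw
    heights <- ic[j] * f[, j] * scale
    ord <- order(heights)           # tallest drawn last, on top
    y <- base
    for (b in .DNA_BASES[ord]) {
      hb <- heights[[b]]
      if (hb < 0.5) next
      y <- y - hb
      svg <- c(svg, sprintf(
        '<text x="%d" y="%.1f" font-family="monospace" font-weight="bold" font-size="%.1f" fill="%s" textLength="%d" lengthAdjust="spacingAndGlyphs">%s</text>',
        x0, y + hb, hb * 1.05, cols[[b]], colw - 4, b))
    }
    lab <- colnames(x@counts)[j]
    svg <- c(svg, sprintf(
      '<text x="%d" y="%d" font-size="8" text-anchor="middle">%s</text>',
      x0 + colw %/% 2, base + 14, lab))
    if (lab %in% c("D1", "D2"))
      svg <- c(svg, sprintf(
        '<rect x="%d" y="%d" width="%d" height="3" fill="#888"/>',
        x0, base + 18, colw - 4))
  }
  svg <- c(svg,
           sprintf('<text x="5" y="%d" font-size="9">bits 0-2</text>', base),
           '</svg>')
  writeLines(svg, path)
  invisible(path)
}
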