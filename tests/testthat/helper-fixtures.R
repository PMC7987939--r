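## Shared fixtures and independent oracles for the test suite.

suppressPackageStartupMessages({
  library(Biostrings)
  library(GenomicRanges)
})

## deterministic random genome as a named DNAStringSet
random_genome <- function(len, seed, gc = 0.5, name = "chr1") {
  set.seed(seed)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = p),
             collapse = "")
  DNAStringSet(setNames(s, name))
}

## site key used to compare called sites with simulator truth
site_keys <- function(sites) {
  paste(as.character(seqnames(sites)), as.integer(start(sites)) - 1L,
        as.character(strand(sites)), mcols(sites)$side)
}
truth_keys <- function(ts) {
  paste(ts$chrom, as.integer(ts$dinucStart0), ts$strand, ts$side)
}

## Independent exhaustive-alignment oracle: full Hamming scan over all
## positions and both strands via Biostrings::matchPattern, never
## through the package's k-mer index path.
oracle_map <- function(genome, fragment, maxMismatches) {
  hits <- list()
  for (str in c("+", "-")) {
    pat <- DNAString(fragment)
    if (str == "-") pat <- reverseComplement(pat)
    for (cn in names(genome)) {
      m <- matchPattern(pat, genome[[cn]], max.mismatch = maxMismatches,
                        with.indels = FALSE)
      if (!length(m)) next
      mm <- neditStartingAt(pat, genome[[cn]], starting.at = start(m),
                            with.indels = FALSE)
      keep <- mm <= maxMismatches   # matchPattern can return edge hits
      if (any(keep))
        hits[[length(hits) + 1L]] <-
          data.frame(chrom = cn, start0 = start(m)[keep] - 1L,
                     strand = str, mm = mm[keep])
    }
  }
  if (!length(hits))
    return(list(status = "unmapped", chrom = NA, start0 = NA,
                strand = NA, mismatches = NA))
  h <- do.call(rbind, hits)
  h <- unique(h)
  best <- h[h$mm == min(h$mm), , drop = FALSE]
  if (nrow(best) > 1L)
    return(list(status = "ambiguous", chrom = NA, start0 = NA,
                strand = NA, mismatches = NA))
  list(status = "unique", chrom = best$chrom, start0 = best$start0,
       strand = best$strand, mismatches = best$mm)
}

## substitute bases at given 1-based positions of a string
mutate_at <- function(seq, pos, bases) {
  for (i in seq_along(pos)) substr(seq, pos[i], pos[i]) <- bases[i]
  seq
}

## Printed per-dinucleotide counts of published junction libraries,
## used to check the tabulation arithmetic.
published_counts <- list(
  SB100X_Left = c(TA = 29748, CA = 10, TG = 7, TT = 4, AA = 5, GA = 4,
                  TC = 8, AG = 2, CT = 7, GG = 4, CC = 4, AT = 5,
                  GT = 2, AC = 1, GC = 7, CG = 0),
  SB100X_Right = c(TA = 27740, CA = 3, TG = 5, TT = 8, AA = 9, GA = 9,
                   TC = 1, AG = 2, CT = 3, GG = 4, CC = 5, AT = 6,
                   GT = 2, AC = 0, GC = 1, CG = 0),
  SB11_Left = c(TA = 3731, CA = 8, TG = 5, TT = 1, TC = 3, AG = 1,
                CT = 3, CC = 3, GT = 1, GC = 3),
  SB11_Right = c(TA = 460, TG = 2, TT = 2, GG = 1, CC = 2, GT = 1,
                 GC = 1),
  Left_mut = c(TA = 39, TG = 3, GA = 1, TC = 2, AG = 1, GG = 1,
               AT = 1, GC = 1),
  Right_mut = c(TA = 73, TG = 1, TT = 2, AA = 1, TC = 2, CT = 1,
                GG = 1, AT = 1, GC = 1),
  recellularized_colon = c(TA = 19084, AT = 2139, TG = 2038, TC = 1913,
                           CA = 1903, AG = 1798, TT = 1778, CC = 1659,
                           AA = 1526, AC = 1395, GG = 1374, CT = 1281,
                           GA = 1271, GC = 1087, GT = 1056, CG = 127))

## fresh registry for tests that register constructs
with_fresh_registry <- function(code) {
  on.exit(resetConstructRegistry())
  resetConstructRegistry()
  force(code)
}
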