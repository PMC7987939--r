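test_that("the k-mer index records every occurrence found by naive scan", {
  g <- DNAStringSet(c(c1 = "ACGTACGT"))
  idx <- buildKmerIndex(g, k = 8)  # k must be >= 8; whole contig
  expect_identical(idx@index$pos, 0L)
  # naive-scan completeness on a random genome
  gg <- random_genome(5000, seed = 31)
  k <- 10L
  idx <- buildKmerIndex(gg, k)
  s <- as.character(gg)[[1]]
  set.seed(8)
  for (i in 1:25) {
    pos0 <- sample(0:(nchar(s) - k), 1)
    kmer <- substr(s, pos0 + 1, pos0 + k)
    naive <- which(vapply(0:(nchar(s) - k), function(p)
      substr(s, p + 1, p + k) == kmer, logical(1))) - 1L
    hits <- sort(idx@index[kmer, on = "kmer"]$pos)
    expect_identical(hits, naive)
  }
  # deterministic rebuilds
  idx2 <- buildKmerIndex(gg, k)
  expect_identical(idx@index, idx2@index)
  expect_error(buildKmerIndex(gg, 4), "8..16")
  expect_error(buildKmerIndex(DNAStringSet(c(tiny = strrep("ACGT", 2500),
                                             small = "ACGTACGTAC")), 12),
               "shortest contig")
})

test_that("unique, ambiguous, reverse-complement and unmapped fragments
           are classified with exact coordinates", {
  g <- random_genome(20000, seed = 77)
  s <- as.character(g)[[1]]
  idx <- buildKmerIndex(g)
  frag <- substr(s, 5001, 5040)
  a <- mapFragment(idx, g, frag)
  expect_identical(a$status, "unique")
  expect_identical(a$start0, 5000L)
  expect_identical(a$strand, "+")
  expect_identical(a$mismatches, 0L)

  rc <- mapFragment(idx, g, revcomp(frag))
  expect_identical(rc$status, "unique")
  expect_identical(rc$start0, 5000L)
  expect_identical(rc$strand, "-")

  # duplicated locus -> ambiguous
  dup <- DNAStringSet(c(c1 = paste0(s, substr(s, 5001, 5100))))
  idx2 <- buildKmerIndex(dup)
  amb <- mapFragment(idx2, dup, substr(s, 5001, 5040))
  expect_identical(amb$status, "ambiguous")
  expect_true(is.na(amb$start0))

  rnd <- mapFragment(idx, g, strrep("ACGT", 10))
  expect_true(rnd$status %in% c("unmapped", "ambiguous", "unique"))
  none <- mapFragment(idx, g, paste0(strrep("A", 20), strrep("C", 20)))
  expect_identical(none$status, "unmapped")
})

test_that("strand consistency: a fragment and its reverse complement map
           to the same locus with opposite strands", {
  g <- random_genome(30000, seed = 101)
  s <- as.character(g)[[1]]
  idx <- buildKmerIndex(g)
  set.seed(6)
  for (i in 1:15) {
    pos0 <- sample(0:(nchar(s) - 50), 1)
    frag <- substr(s, pos0 + 1, pos0 + 50)
    a <- mapFragment(idx, g, frag)
    b <- mapFragment(idx, g, revcomp(frag))
    expect_identical(a$status, "unique")
    expect_identical(a$start0, b$start0)
    expect_identical(a$chrom, b$chrom)
    expect_true(a$strand != b$strand)
  }
})

test_that("fragments cut from unique loci round-trip to their origin", {
  g <- random_genome(40000, seed = 55)
  s <- as.character(g)[[1]]
  idx <- buildKmerIndex(g)
  set.seed(12)
  pos0 <- sample(0:(nchar(s) - 45), 200)
  frags <- setNames(substring(s, pos0 + 1, pos0 + 45),
                    paste0("f", seq_along(pos0)))
  res <- mapFragments(idx, g, frags)
  uq <- res$status == "unique"
  expect_gt(mean(uq), 0.99)  # random 45-mers are essentially all unique
  expect_identical(res$start0[uq], pos0[uq])
  expect_true(all(res$strand[uq] == "+"))
  expect_true(all(res$mismatches[uq] == 0L))
})

test_that("SAM import converts coordinates, flags and MAPQ thresholds", {
  g <- random_genome(1000, seed = 3)
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6",
    "@SQ\tSN:chr1\tLN:1000",
    paste("r1", 0, "chr1", 100, 42, "10M", "*", 0, 0,
          "ACGTACGTAC", "IIIIIIIIII", "NM:i:1", sep = "\t"),
    paste("r2", 4, "*", 0, 0, "*", "*", 0, 0,
          "ACGTACGTAC", "IIIIIIIIII", sep = "\t"),
    paste("r3", 16, "chr1", 200, 40, "10M", "*", 0, 0,
          "ACGTACGTAC", "IIIIIIIIII", sep = "\t"),
    paste("r4", 0, "chr1", 300, 5, "10M", "*", 0, 0,
          "ACGTACGTAC", "IIIIIIIIII", sep = "\t")), sam)
  a <- importSam(sam, "left", g)
  a <- a[match(c("r1", "r2", "r3", "r4"), a$id), ]
  expect_identical(a$status, c("unique", "unmapped", "unique", "ambiguous"))
  expect_identical(a$start0[1], 99L)       # SAM POS 100 -> 0-based 99
  expect_identical(a$strand[3], "-")       # FLAG 16
  expect_identical(a$mismatches[1], 1L)    # NM tag
  expect_identical(a$side, rep("left", 4))

  # contig absent from the reference
  bad <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:chrX\tLN:500",
               paste("r1", 0, "chrX", 10, 42, "10M", "*", 0, 0,
                     "ACGTACGTAC", "IIIIIIIIII", sep = "\t")), bad)
  expect_error(importSam(bad, "left", g), "absent from the reference")

  # header-less SAM is rejected
  noh <- withr::local_tempfile(fileext = ".sam")
  writeLines(paste("r1", 0, "chr1", 10, 42, "10M", "*", 0, 0,
                   "ACGTACGTAC", "IIIIIIIIII", sep = "\t"), noh)
  expect_error(importSam(noh, "left", g), "SAM")
})

test_that("alignment filtering keeps unique long fragments and balances
           its ledger", {
  aln <- data.frame(
    id = paste0("r", 1:5), side = "left",
    status = c("unique", "ambiguous", "unmapped", "unique", "unique"),
    chrom = c("c1", NA, NA, "c1", "c1"),
    start0 = c(10L, NA, NA, 50L, 80L),
    strand = c("+", NA, NA, "-", "+"),
    mismatches = c(0L, NA, NA, 1L, 0L),
    len = c(40L, 40L, 40L, 40L, 10L))
  out <- filterAlignments(aln, minFragmentLen = 20)
  expect_identical(out$kept$id, c("r1", "r4"))
  expect_identical(unname(out$stats),
                   c(5L, 2L, 1L, 1L, 1L))
  expect_identical(out$stats[["kept"]] + out$stats[["droppedUnmapped"]] +
                     out$stats[["droppedAmbiguous"]] +
                     out$stats[["droppedShort"]], out$stats[["input"]])
  # all-unique input passes untouched when long enough
  ok <- filterAlignments(aln[c(1, 4), ])
  expect_identical(nrow(ok$kept), 2L)
  # ambiguous records survive when uniqueness is not required
  noreq <- filterAlignments(aln, requireUnique = FALSE)
  expect_true("r2" %in% noreq$kept$id)
})
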