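mk_site <- function(chrom, pos0, strand, side = "left", dinuc = "TA") {
  gr <- GRanges(chrom, IRanges(pos0 + 1L, width = 2L), strand = strand)
  mcols(gr)$side <- side
  mcols(gr)$dinucleotide <- dinuc
  mcols(gr)$isTA <- dinuc == "TA"
  gr
}

test_that("flank windows are extracted strand-normalized around the
           dinucleotide", {
  #            0123456789
  g <- DNAStringSet(c(c1 = "GGCATAGTCC"))
  s <- mk_site("c1", 4L, "+")            # TA at 4..5
  fl <- extractFlanks(g, s, W = 2)
  expect_identical(fl$windows, "CATAGT")  # -2,-1,D1,D2,+1,+2

  # minus-strand site over the same interval: reverse complement
  sm <- mk_site("c1", 4L, "-")
  expect_identical(extractFlanks(g, sm, W = 2)$windows, "ACTATG")

  # mirrored fixture: planting the revcomp context at a minus site
  # reproduces the identical window string
  g2 <- DNAStringSet(c(c1 = paste0("GG", revcomp("CATAGT"), "CC")))
  s2 <- mk_site("c1", 4L, "-")
  expect_identical(extractFlanks(g2, s2, W = 2)$windows, "CATAGT")

  # windows too close to the edge, or containing N, are excluded
  edge <- mk_site("c1", 1L, "+")
  out <- extractFlanks(g, edge, W = 10)
  expect_identical(out$windows, character())
  expect_identical(out$excludedBounds, 1L)
  gN <- DNAStringSet(c(c1 = "GGCNTAGTCC"))
  outN <- extractFlanks(gN, mk_site("c1", 4L, "+"), W = 2)
  expect_identical(outN$excludedN, 1L)
})

test_that("PFM construction, consensus and tie handling follow the counts", {
  p1 <- buildPFM("TATA", pseudocount = 0)
  expect_identical(paste(pfmConsensus(p1), collapse = ""), "TATA")
  expect_equal(unname(informationContent(p1)), rep(2, 4))

  p2 <- buildPFM(c("AAAA", "CCCC"), pseudocount = 0)
  expect_true(all(pfmConsensus(p2) == "N"))
  expect_equal(unname(baseFrequencies(p2)["A", ]), rep(0.5, 4))

  expect_error(buildPFM(character()), "no windows")
  expect_error(buildPFM(c("AAAA", "AAA")), "length")
  expect_error(buildPFM("AANA"), "A,C,G,T")
})

test_that("information content reproduces its closed forms", {
  # uniform column -> 0 bits; pure column -> 2 bits; (1/2,1/2,0,0) -> 1 bit
  u <- buildPFM(c("AA", "CC", "GG", "TT"), pseudocount = 0)
  expect_equal(unname(informationContent(u)), c(0, 0))
  pure <- buildPFM(rep("GG", 4), pseudocount = 0)
  expect_equal(unname(informationContent(pure)), c(2, 2))
  half <- buildPFM(c("AA", "AA", "CC", "CC"), pseudocount = 0)
  expect_equal(unname(informationContent(half)), c(1, 1))
  expect_error(informationContent(u, background = c(1, 1, 1, 1)),
               "summing to 1")
  # frequencies always sum to 1; IC in [0,2] with pseudocount
  set.seed(4)
  win <- vapply(1:30, function(i)
    paste(sample(c("A", "C", "G", "T"), 8, TRUE), collapse = ""),
    character(1))
  p <- buildPFM(win, pseudocount = 0.1)
  expect_equal(unname(colSums(baseFrequencies(p))), rep(1, 8))
  ic <- informationContent(p)
  expect_true(all(ic >= 0 & ic <= 2 + 1e-12))
  expect_true(all(informationContent(p, smallSampleCorrection = TRUE) <= ic))
})

test_that("combining sides reverse-complements the right library", {
  set.seed(14)
  left <- vapply(1:20, function(i)
    paste(sample(c("A", "C", "G", "T"), 10, TRUE), collapse = ""),
    character(1))
  # right windows that are exact revcomps of the left ones collapse onto
  # the same PFM with doubled n
  both <- combineSides(left, revcomp(left), pseudocount = 0)
  lone <- buildPFM(left, pseudocount = 0)
  expect_identical(nSequences(both), 2L * nSequences(lone))
  expect_identical(pfmConsensus(both), pfmConsensus(lone))
  expect_equal(pfmCounts(both), 2L * pfmCounts(lone))
  # empty right list: combined equals the left PFM
  expect_equal(pfmCounts(combineSides(left, character())),
               pfmCounts(lone))
  expect_error(combineSides(left, "ACGT"), "lengths differ")
})

test_that("consensus-to-motif matching counts ties as mismatches", {
  win <- c("CCGGTAACTG")  # W = 4; D1 D2 = TA; distal +1..+4 = ACTG
  p <- buildPFM(rep(win, 5), pseudocount = 0)
  expect_identical(endMatchScore(p, "ACTG"), 1)
  expect_identical(endMatchScore(p, "ACGG"), 0.75)
  expect_identical(endMatchScore(p, "AGGC"), 0.25)
  expect_error(endMatchScore(p, "ACTGA", offset = 2), "overruns")
  # uniform pfm: all ties -> score 0
  u <- buildPFM(c("AAAAAAAAAA", "CCCCCCCCCC", "GGGGGGGGGG", "TTTTTTTTTT"),
                pseudocount = 0)
  expect_identical(endMatchScore(u, "ACTG"), 0)
  # offset -1 starts the comparison at D1
  expect_identical(endMatchScore(p, "TAAC", offset = -1), 1)
  expect_identical(endMatchScore(p, "GTA", offset = -2), 1)
})

test_that("side bias is zero for symmetric profiles and flips sign when
           the window is mirrored", {
  sym <- buildPFM(rep("GGTTAAGG", 6), pseudocount = 0.1)
  expect_equal(sideBias(sym, L = 2), 0)
  asym <- buildPFM(rep(c("AATTTACTGC", "ACTTTACTGC", "AGTTTACTGC",
                         "ATTTTACTGC"), 5), pseudocount = 0.1)
  b <- sideBias(asym, L = 4)
  expect_gt(b, 0)
  mirrored <- buildPFM(revcomp(rep(c("AATTTACTGC", "ACTTTACTGC",
                                     "AGTTTACTGC", "ATTTTACTGC"), 5)),
                       pseudocount = 0.1)
  expect_equal(sideBias(mirrored, L = 4), -b)
})

test_that("PFM and logo files are written with position labels", {
  p <- buildPFM(rep("CCGGTAACTG", 4))
  f <- withr::local_tempfile(fileext = ".tsv")
  writePFM(p, f)
  tab <- read.delim(f, skip = 1)
  expect_identical(tab$position,
                   c("-4", "-3", "-2", "-1", "D1", "D2", "+1", "+2",
                     "+3", "+4"))
  expect_identical(tab$consensus[7:10], c("A", "C", "T", "G"))
  svg <- withr::local_tempfile(fileext = ".svg")
  writeLogoSVG(p, svg, "toy")
  expect_true(any(grepl("<svg", readLines(svg))))
})
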