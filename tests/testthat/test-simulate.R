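params_small <- function(...) {
  defaults <- list(genomeLength = 5e4, nEvents = 100L, pNonTA = 0.1,
                   motifMatchProb = 1, readLength = 60L, errorRate = 0,
                   dupLambda = 0, seed = 42L)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulationParams, args)
}

test_that("genome generation is deterministic and honours GC", {
  p <- params_small()
  g1 <- generateGenome(p)
  g2 <- generateGenome(p)
  expect_identical(as.character(g1), as.character(g2))
  g3 <- generateGenome(params_small(seed = 43L))
  expect_false(identical(as.character(g1), as.character(g3)))

  at <- generateGenome(params_small(gc = 0))
  expect_true(grepl("^[AT]+$", as.character(at)[[1]]))
})

test_that("TA dinucleotide frequency matches the i.i.d. closed form", {
  # at GC 0.5, P(TA at a position) = 1/16; TA cannot overlap itself,
  # so the count is close to binomial with sd ~ sqrt(L p (1-p))
  L <- 1e5
  g <- generateGenome(params_small(genomeLength = L, seed = 7L))
  n_ta <- length(gregexpr("TA", as.character(g)[[1]], fixed = TRUE)[[1]])
  expected <- (L - 1) / 16
  sd <- sqrt(L * (1 / 16) * (15 / 16))
  expect_lt(abs(n_ta - expected), 5 * sd)
})

test_that("pNonTA = 0 gives only canonical TA events", {
  p <- params_small(pNonTA = 0)
  g <- generateGenome(p)
  ev <- simulateIntegrations(g, getConstruct("pYT11"), p)
  expect_true(all(ev$class == "canonical"))
  expect_true(all(ev$leftDinuc == "TA" & ev$rightDinuc == "TA"))
  expect_true(all(ev$aberrantSide == "none"))
  # events sit on genomic TA dinucleotides
  gc <- as.character(g)[[1]]
  expect_true(all(substring(gc, ev$pos0 + 1, ev$pos0 + 2) == "TA"))
})

test_that("forced aberrant events plant the end motif on the distal flank", {
  p <- params_small(pNonTA = 1, motifMatchProb = 1, nEvents = 40L)
  g <- generateGenome(p)
  construct <- getConstruct("pYT23")
  ev <- simulateIntegrations(g, construct, p)
  expect_true(all(ev$class == "aberrant"))
  # exactly one junction is non-TA, the other stays TA
  nonTA_left <- ev$leftDinuc != "TA"
  nonTA_right <- ev$rightDinuc != "TA"
  expect_true(all(xor(nonTA_left, nonTA_right)))
  expect_identical(ifelse(nonTA_left, "left", "right"), ev$aberrantSide)

  # reconstruct each aberrant junction fragment and check the bases at
  # offsets +1..+4 equal the motif exactly (motifMatchProb = 1)
  gc <- as.character(g)[[1]]
  for (i in seq_len(nrow(ev))) {
    side <- ev$aberrantSide[i]
    q <- ev$pos0[i]
    plusLike <- (side == "right") == (ev$strand[i] == "+")
    frag <- if (plusLike) substring(gc, q + 1, q + 6)
            else revcomp(substring(gc, q - 3, q + 2))
    expect_identical(substr(frag, 1, 2),
                     if (side == "left") ev$leftDinuc[i] else ev$rightDinuc[i])
    expect_identical(substr(frag, 3, 6), deriveEndMotif(construct, side))
  }
})

test_that("realized aberrant fraction matches the planted probability", {
  p <- params_small(genomeLength = 2e5, nEvents = 2000L, pNonTA = 0.05,
                    motifMatchProb = 0.8, seed = 19L)
  g <- generateGenome(p)
  ev <- simulateIntegrations(g, getConstruct("pYT11"), p)
  k <- sum(ev$class == "aberrant")
  ci <- stats::binom.test(k, nrow(ev))$conf.int
  expect_true(ci[1] <= 0.05 && 0.05 <= ci[2])
})

test_that("reads are end + flank with deterministic FASTQ output", {
  p <- params_small(nEvents = 30L, pNonTA = 0)
  construct <- getConstruct("pYT11")
  g <- generateGenome(p)
  ev <- simulateIntegrations(g, construct, p)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- eventsToReads(ev, g, construct, p, d1)
  r2 <- eventsToReads(ev, g, construct, p, d2)
  # byte-identical FASTQ and truth given identical params + seed
  expect_identical(readLines(r1$leftFastq), readLines(r2$leftFastq))
  expect_identical(readLines(r1$rightFastq), readLines(r2$rightFastq))
  expect_identical(readLines(r1$truthTsv), readLines(r2$truthTsv))

  # error-free canonical reads: post-end prefix is TA + reference bases
  reads <- readDNAStringSet(r1$rightFastq, format = "fastq")
  endLen <- nchar(rightEnd(construct))
  gc <- as.character(g)[[1]]
  seqs <- as.character(reads)
  expect_true(all(substr(seqs, 1, endLen) == rightEnd(construct)))
  i <- ev$strand == "+"
  frag <- substr(seqs, endLen + 1, nchar(seqs))
  expect_true(all(substr(frag, 1, 2) == "TA"))
  expect_identical(unname(frag[i][1]),
                   substring(gc, ev$pos0[i][1] + 1,
                             ev$pos0[i][1] + p@readLength - endLen))
})

test_that("duplicate and error models change read counts and bases", {
  p <- params_small(nEvents = 50L, pNonTA = 0, dupLambda = 2)
  construct <- getConstruct("pYT11")
  g <- generateGenome(p)
  ev <- simulateIntegrations(g, construct, p)
  r <- eventsToReads(ev, g, construct, p, withr::local_tempdir())
  expect_gt(r$nReads[["left"]], 50L)  # duplicates inflate counts

  pe <- params_small(nEvents = 50L, pNonTA = 0, errorRate = 0.05)
  re <- eventsToReads(ev, g, construct, pe, withr::local_tempdir())
  r0 <- eventsToReads(ev, g, construct,
                      params_small(nEvents = 50L, pNonTA = 0),
                      withr::local_tempdir())
  s_err <- as.character(readDNAStringSet(re$leftFastq, format = "fastq"))
  s_clean <- as.character(readDNAStringSet(r0$leftFastq, format = "fastq"))
  expect_identical(length(s_err), length(s_clean))
  expect_gt(sum(s_err != s_clean), 0L)
})

test_that("truth round-trips through the TSV and maps to per-side sites", {
  p <- params_small(nEvents = 60L, pNonTA = 0.3)
  construct <- getConstruct("pYT11")
  g <- generateGenome(p)
  ev <- simulateIntegrations(g, construct, p)
  r <- eventsToReads(ev, g, construct, p, withr::local_tempdir())
  back <- readTruth(r$truthTsv)
  expect_identical(back, ev)
  ts <- truthSites(ev)
  expect_identical(nrow(ts), 2L * nrow(ev))
  # aberrant events: non-TA key on the aberrant side only
  ab <- ev[ev$class == "aberrant", ]
  for (i in seq_len(nrow(ab))) {
    side <- ab$aberrantSide[i]
    other <- setdiff(c("left", "right"), side)
    k <- ts[ts$side == side & ts$dinucStart0 == ab$pos0[i], ]
    expect_true(all(k$dinucleotide != "TA"))
    k2 <- ts[ts$side == other & ts$dinucStart0 == ab$otherPos0[i], ]
    expect_true(all(k2$dinucleotide == "TA"))
  }
})
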