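#' Construct simulation parameters
#'
#' See [SimulationParams] for the meaning and rationale of each
#' parameter. The seed is mandatory and drives every random draw, so
#' identical parameters give byte-identical FASTQ and truth files.
#'
#' @param genomeLength chromosome length(s) in bp (each >= 1 kb).
#' @param gc GC fraction.
#' @param nEvents number of integration events.
#' @param pNonTA per-event aberrant (non-TA) probability.
#' @param motifMatchProb per-base probability the aberrant distal flank
#'   matches the end motif.
#' @param readLength junction read length.
#' @param errorRate per-base substitution error rate.
#' @param dupLambda duplicate reads per junction are 1 + Poisson(this).
#' @param excludeCpG exclude CG from the non-TA draw.
#' @param bothSidesNonTA aberrant events non-TA at both junctions.
#' @param distinctSites sample integration positions without
#'   replacement.
#' @param seed integer seed (mandatory).
#' @return a [SimulationParams] object.
#' @export
simulationParams <- function(genomeLength = 1e6, gc = 0.5,
                             nEvents = 20000, pNonTA = 0.014,
                             motifMatchProb = 0.8, readLength = 60,
                             errorRate = 0.001, dupLambda = 0.5,
                             excludeCpG = FALSE, bothSidesNonTA = FALSE,
                             distinctSites = TRUE, seed) {
  if (missing(seed)) stop("simulationParams: seed is mandatory")
  new("SimulationParams", genomeLength = as.numeric(genomeLength),
      gc = gc, nEvents = as.integer(nEvents), pNonTA = pNonTA,
      motifMatchProb = motifMatchProb, readLength = as.integer(readLength),
      errorRate = errorRate, dupLambda = dupLambda,
      excludeCpG = excludeCpG, bothSidesNonTA = bothSidesNonTA,
      distinctSites = distinctSites, seed = as.integer(seed))
}

.count_fixed <- function(pattern, subject) {
  m <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (m[1] == -1L) 0L else length(m)
}

#' Generate a synthetic reference genome
#'
#' I.i.d. bases at the stated GC fraction, one chromosome per entry of
#' `genomeLength` (named chr1, chr2, ...). Deterministic given the
#' seed. Chromosomes are resampled (bounded retries) if they fall
#' below an average of one TA per 200 bp, which the downstream
#' integration model requires.
#'
#' @param params a [SimulationParams].
#' @return named [Biostrings::DNAStringSet].
#' @export
generateGenome <- function(params) {
  stopifnot(is(params, "SimulationParams"))
  set.seed(params@seed)
  p <- c(A = (1 - params@gc) / 2, C = params@gc / 2,
         G = params@gc / 2, T = (1 - params@gc) / 2)
  chroms <- vapply(params@genomeLength, function(len) {
    if (len < 1) stop("generateGenome: zero-length chromosome")
    for (try in 1:20) {
      s <- paste(sample(.DNA_BASES, len, replace = TRUE, prob = p),
                 collapse = "")
      if (.count_fixed("TA", s) >= len / 200) return(s)
    }
    stop("generateGenome: could not reach the required TA density ",
         "(>= 1 per 200 bp) at GC = ", params@gc)
  }, character(1))
  names(chroms) <- paste0("chr", seq_along(chroms))
  DNAStringSet(chroms)
}

.NONTA <- setdiff(DINUCLEOTIDE_ORDER, "TA")

## Sorted 0-based TA dinucleotide positions per chromosome.
.ta_positions <- function(gchr) {
  lapply(gchr, function(s) {
    m <- gregexpr("TA", s, fixed = TRUE)[[1]]
    if (m[1] == -1L) integer() else as.integer(m) - 1L
  })
}

#' Simulate ground-truth integration events
#'
#' With probability `1 - pNonTA` an event is canonical: placed at a
#' uniformly chosen TA dinucleotide (both junctions resolve at that
#' TA, as for a clean target-site duplication). With probability
#' `pNonTA` it is aberrant: one uniformly chosen side carries a non-TA
#' dinucleotide (uniform over the 15 non-TA dinucleotides, CG optionally
#' excluded) and the event is placed, by rejection sampling over
#' genomic loci, so that the bases at offsets +1..+L on the distal side
#' of that junction match the sequenced side's end motif independently
#' with probability `motifMatchProb` per position; the junction on the
#' other side still resolves at a TA (the nearest unused one), so non-TA
#' dinucleotides occur at one side only.
#'
#' @param genome named [Biostrings::DNAStringSet] (or named character).
#' @param construct a [TransposonConstruct].
#' @param params a [SimulationParams].
#' @return data.frame with one row per event: `chrom`, `pos0` (0-based
#'   position of the first base of the event's target dinucleotide),
#'   `strand`, `class` (canonical/aberrant), `leftDinuc`, `rightDinuc`
#'   (as read in each library), `aberrantSide` (left/right/none) and
#'   `otherPos0` (junction position of the non-aberrant side; equals
#'   `pos0` for canonical events).
#' @export
simulateIntegrations <- function(genome, construct, params) {
  stopifnot(is(params, "SimulationParams"),
            is(construct, "TransposonConstruct"))
  set.seed(params@seed + 1L)
  gchr <- .genome_chr(genome)
  L <- nchar(construct@endMotif)
  margin <- params@readLength + 30L
  lens <- nchar(gchr)

  ta <- .ta_positions(gchr)
  eligible <- lapply(names(gchr), function(cn) {
    p <- ta[[cn]]
    p[p >= margin & p <= lens[[cn]] - margin]
  })
  names(eligible) <- names(gchr)
  pool <- data.frame(chrom = rep(names(gchr), lengths(eligible)),
                     pos0 = unlist(eligible, use.names = FALSE),
                     stringsAsFactors = FALSE)
  if (nrow(pool) == 0L)
    stop("simulateIntegrations: no eligible TA site in the genome")
  taken <- rep(FALSE, nrow(pool))        # TA pool bookkeeping
  usedPos <- new.env(parent = emptyenv()) # every occupied locus

  n <- params@nEvents
  isAb <- runif(n) < params@pNonTA
  strandv <- sample(c("+", "-"), n, replace = TRUE)

  nCan <- sum(!isAb)
  if (params@distinctSites && nCan > nrow(pool))
    stop("simulateIntegrations: more canonical events than eligible TA sites")
  canIdx <- sample.int(nrow(pool), nCan, replace = !params@distinctSites)
  taken[canIdx] <- TRUE
  for (i in canIdx)
    assign(paste0(pool$chrom[i], ":", pool$pos0[i]), TRUE, envir = usedPos)

  chrom <- character(n); pos0 <- integer(n); otherPos0 <- integer(n)
  leftD <- character(n); rightD <- character(n); abSide <- character(n)

  ci <- canIdx
  chrom[!isAb] <- pool$chrom[ci]
  pos0[!isAb] <- pool$pos0[ci]
  otherPos0[!isAb] <- pool$pos0[ci]
  leftD[!isAb] <- "TA"; rightD[!isAb] <- "TA"; abSide[!isAb] <- "none"

  nonTA <- if (params@excludeCpG) setdiff(.NONTA, "CG") else .NONTA
  patCache <- new.env(parent = emptyenv())
  find_pattern <- function(pat) {
    if (!is.null(hits <- patCache[[pat]])) return(hits)
    hits <- do.call(rbind, lapply(names(gchr), function(cn) {
      m <- gregexpr(pat, gchr[[cn]], fixed = TRUE)[[1]]
      if (m[1] == -1L) NULL
      else data.frame(chrom = cn, start0 = as.integer(m) - 1L,
                      stringsAsFactors = FALSE)
    }))
    if (is.null(hits))
      hits <- data.frame(chrom = character(), start0 = integer())
    patCache[[pat]] <- hits
    hits
  }
  nearest_free_ta <- function(cn, q) {
    idx <- which(pool$chrom == cn)
    if (!length(idx)) stop("simulateIntegrations: no TA on ", cn)
    ppos <- pool$pos0[idx]
    o <- order(abs(ppos - q))
    for (j in o) {
      i <- idx[j]
      if (!params@distinctSites || !taken[i]) return(i)
    }
    stop("simulateIntegrations: TA pool exhausted on ", cn)
  }
  place_junction <- function(side, strand) {
    # returns list(chrom, pos0, dinuc) for one aberrant junction
    for (attempt in 1:25) {
      dinuc <- sample(nonTA, 1L)
      motif <- deriveEndMotif(construct, side)
      mb <- strsplit(motif, "")[[1]]
      realized <- vapply(mb, function(b) {
        if (runif(1) < params@motifMatchProb) b
        else sample(setdiff(.DNA_BASES, b), 1L)
      }, character(1))
      r <- paste0(dinuc, paste(realized, collapse = ""))
      needRC <- (side == "left") == (strand == "+")
      pat <- if (needRC) .revcomp_chr(r) else r
      hits <- find_pattern(pat)
      if (!nrow(hits)) next
      q <- if (needRC) hits$start0 + L else hits$start0
      ok <- q >= margin & q <= lens[hits$chrom] - margin
      if (any(ok)) {
        keys <- paste0(hits$chrom, ":", q)
        ok <- ok & !vapply(keys, function(k)
          isTRUE(usedPos[[k]]), logical(1))
      }
      if (!any(ok)) next
      pick <- sample(which(ok), 1L)
      assign(paste0(hits$chrom[pick], ":", q[pick]), TRUE, envir = usedPos)
      return(list(chrom = hits$chrom[pick], pos0 = q[pick], dinuc = dinuc))
    }
    stop("simulateIntegrations: could not place an aberrant junction ",
         "matching the end-motif constraint (side ", side,
         ") after bounded rejections")
  }

  for (i in which(isAb)) {
    side <- sample(c("left", "right"), 1L)
    j1 <- place_junction(side, strandv[i])
    chrom[i] <- j1$chrom; pos0[i] <- j1$pos0; abSide[i] <- side
    other <- if (side == "left") "right" else "left"
    if (params@bothSidesNonTA) {
      j2 <- place_junction(other, strandv[i])
      if (j2$chrom != j1$chrom) { # keep both junctions on one contig
        chrom[i] <- j1$chrom
      }
      otherPos0[i] <- j2$pos0
      if (side == "left") { leftD[i] <- j1$dinuc; rightD[i] <- j2$dinuc }
      else { rightD[i] <- j1$dinuc; leftD[i] <- j2$dinuc }
    } else {
      k <- nearest_free_ta(j1$chrom, j1$pos0)
      taken[k] <- TRUE
      assign(paste0(pool$chrom[k], ":", pool$pos0[k]), TRUE, envir = usedPos)
      otherPos0[i] <- pool$pos0[k]
      if (side == "left") { leftD[i] <- j1$dinuc; rightD[i] <- "TA" }
      else { rightD[i] <- j1$dinuc; leftD[i] <- "TA" }
    }
  }

  data.frame(chrom = chrom, pos0 = pos0, strand = strandv,
             class = ifelse(isAb, "aberrant", "canonical"),
             leftDinuc = leftD, rightDinuc = rightD,
             aberrantSide = abSide, otherPos0 = otherPos0,
             stringsAsFactors = FALSE)
}

## apply i.i.d. substitution errors to reads
.add_substitutions <- function(reads, rate) {
  if (rate <= 0 || !length(reads)) return(reads)
  len <- nchar(reads)
  nerr <- rbinom(length(reads), len, rate)
  for (i in which(nerr > 0L)) {
    pos <- sample.int(len[i], nerr[i])
    ch <- strsplit(reads[i], "")[[1]]
    ch[pos] <- vapply(ch[pos], function(b)
      sample(setdiff(.DNA_BASES, b), 1L), character(1))
    reads[i] <- paste(ch, collapse = "")
  }
  reads
}

#' Emit junction FASTQ libraries and a truth table for simulated events
#'
#' Every event emits at least one read per sequenced side: the side's
#' transposon end sequence followed by the genomic flank read off the
#' appropriate strand, starting at the junction dinucleotide. Duplicate
#' reads follow 1 + Poisson(`dupLambda`); substitution errors are
#' i.i.d. at `errorRate`; qualities are constant Q30. Events too close
#' to a contig edge to extract the flank are skipped and counted.
#'
#' @param events data.frame from [simulateIntegrations()].
#' @param genome the genome the events were simulated on.
#' @param construct the [TransposonConstruct] used.
#' @param params the [SimulationParams] used.
#' @param outDir output directory (created if needed).
#' @param prefix file name prefix.
#' @return list with `leftFastq`, `rightFastq`, `truthTsv` (paths),
#'   `nReads` (named integer), and `skipped` (named integer of
#'   edge-skipped junctions per side).
#' @export
eventsToReads <- function(events, genome, construct, params,
                          outDir = tempfile("simreads"), prefix = "sim") {
  stopifnot(is(params, "SimulationParams"))
  set.seed(params@seed + 2L)
  gchr <- .genome_chr(genome)
  lens <- nchar(gchr)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  nReads <- c(left = 0L, right = 0L)
  skipped <- c(left = 0L, right = 0L)

  for (side in c("left", "right")) {
    endSeq <- endSequence(construct, side)
    FL <- params@readLength - nchar(endSeq)
    if (FL <= 20L)
      stop("eventsToReads: readLength must exceed end length + 20")
    # aberrantSide holds the drawn side (left/right) for aberrant
    # events; that junction sits at pos0, the other at otherPos0
    pj <- ifelse(events$class == "canonical" | events$aberrantSide == side,
                 events$pos0, events$otherPos0)
    st <- events$strand
    plusLike <- (side == "right" & st == "+") | (side == "left" & st == "-")
    from <- ifelse(plusLike, pj + 1L, pj + 2L - FL + 1L)
    to   <- ifelse(plusLike, pj + FL, pj + 2L)
    ok <- from >= 1L & to <= lens[events$chrom]
    skipped[side] <- sum(!ok)
    frag <- substring(gchr[events$chrom[ok]], from[ok], to[ok])
    frag[!plusLike[ok]] <- .revcomp_chr(frag[!plusLike[ok]])
    ndup <- 1L + rpois(sum(ok), params@dupLambda)
    ids <- sprintf("%s_e%06d_%s", prefix, which(ok),
                   if (side == "left") "L" else "R")
    reads <- rep(paste0(endSeq, frag), ndup)
    ids <- paste0(rep(ids, ndup), "_d",
                  unlist(lapply(ndup, seq_len), use.names = FALSE))
    reads <- .add_substitutions(reads, params@errorRate)
    fq <- file.path(outDir, paste0(prefix, "_", side, ".fastq"))
    qual <- strrep("?", params@readLength)  # Sanger Q30
    writeXStringSet(DNAStringSet(setNames(reads, ids)), fq,
                    format = "fastq",
                    qualities = BStringSet(rep(qual, length(reads))))
    out[[paste0(side, "Fastq")]] <- fq
    nReads[side] <- length(reads)
  }

  truth <- data.frame(chrom = events$chrom, pos_1based = events$pos0 + 1L,
                      strand = events$strand, class = events$class,
                      left_dinuc = events$leftDinuc,
                      right_dinuc = events$rightDinuc,
                      aberrant_side = events$aberrantSide,
                      other_pos_1based = events$otherPos0 + 1L)
  tp <- file.path(outDir, paste0(prefix, "_truth.tsv"))
  write.table(truth, tp, sep = "\t", quote = FALSE, row.names = FALSE)
  out$truthTsv <- tp
  out$nReads <- nReads
  out$skipped <- skipped
  out
}

#' Read a truth TSV back into the events data.frame form
#' @param path truth TSV written by [eventsToReads()].
#' @return data.frame in the layout of [simulateIntegrations()].
#' @export
readTruth <- function(path) {
  t <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = c(chrom = "character"))
  data.frame(chrom = t$chrom, pos0 = t$pos_1based - 1L, strand = t$strand,
             class = t$class, leftDinuc = t$left_dinuc,
             rightDinuc = t$right_dinuc, aberrantSide = t$aberrant_side,
             otherPos0 = t$other_pos_1based - 1L, stringsAsFactors = FALSE)
}

#' Expected unique integration sites implied by a truth table
#'
#' Converts simulated events to the per-library site keys the pipeline
#' should recover: for each side, the junction dinucleotide position,
#' the alignment strand of the trimmed fragment (the opposite of the
#' event strand for left-junction reads, equal to it for right-junction
#' reads), and the dinucleotide as read.
#'
#' @param events data.frame from [simulateIntegrations()] or
#'   [readTruth()].
#' @return data.frame: `chrom`, `dinucStart0`, `strand`, `side`,
#'   `dinucleotide`.
#' @export
truthSites <- function(events) {
  one <- function(side) {
    pj <- ifelse(events$class == "canonical" | events$aberrantSide == side,
                 events$pos0, events$otherPos0)
    stx <- if (side == "left") chartr("+-", "-+", events$strand)
           else events$strand
    data.frame(chrom = events$chrom, dinucStart0 = pj, strand = stx,
               side = side,
               dinucleotide = if (side == "left") events$leftDinuc
                              else events$rightDinuc,
               stringsAsFactors = FALSE)
  }
  out <- rbind(one("left"), one("right"))
  unique(out)
}

#' Simulate a complete dataset on disk
#'
#' Convenience wrapper: generates the genome, simulates events, writes
#' the reference FASTA, the two junction FASTQ libraries and the truth
#' TSV into `outDir`.
#'
#' @param params a [SimulationParams].
#' @param construct a [TransposonConstruct] (default preset `pYT11`).
#' @param outDir output directory.
#' @param prefix file prefix.
#' @return list: `referencePath`, `leftFastq`, `rightFastq`,
#'   `truthTsv`, `genome`, `events`, `nReads`, `skipped`.
#' @export
simulateDataset <- function(params, construct = getConstruct("pYT11"),
                            outDir = tempfile("simdata"), prefix = "sim") {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  genome <- generateGenome(params)
  events <- simulateIntegrations(genome, construct, params)
  rd <- eventsToReads(events, genome, construct, params, outDir, prefix)
  ref <- file.path(outDir, paste0(prefix, "_reference.fa"))
  writeReference(genome, ref)
  c(list(referencePath = ref, genome = genome, events = events), rd)
}

setMethod("show", "SimulationParams", function(object) {
  cat("SimulationParams\n")
  cat(sprintf("  genome: %s bp (GC %.2f)\n",
              paste(format(object@genomeLength, big.mark = ","),
                    collapse = " + "), object@gc))
  cat(sprintf("  events: %d (pNonTA %.4g, motifMatchProb %.2f)\n",
              object@nEvents, object@pNonTA, object@motifMatchProb))
  cat(sprintf("  reads : length %d, error %.4g, dupLambda %.2f, seed %d\n",
              object@readLength, object@errorRate, object@dupLambda,
              object@seed))
})
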