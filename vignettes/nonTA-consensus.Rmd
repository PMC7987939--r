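---
title: "Calling non-TA Sleeping Beauty integration sites and their end-mimicking consensus"
author: "sbsites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling non-TA Sleeping Beauty integration sites and their end-mimicking consensus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbsites)
```

## The problem

Sleeping Beauty (SB), a Tc1/mariner-family DNA transposon, is the
classic "TA-targeting" genetic tool: canonical integration happens at a
TA dinucleotide, which is duplicated on both sides of the inserted
element. Deep junction sequencing, however, shows a small but
reproducible minority of insertions whose junction dinucleotide is one
of the 15 non-TA dinucleotides. Two properties distinguish these
events from mere noise. First, the non-TA dinucleotide appears at one
junction only, while the other junction of the same event still
resolves at a TA — so a library sequenced from the "good" side counts
the event as canonical. Second, the genomic sequence flanking the
non-TA junction on the side *away* from the sequencing primer shows a
consensus that reproduces the transposon end sequence itself, and
follows the end sequence when the end is mutated. Together these point
at aberrant integration products in which one transposon end interacts
with target DNA that resembles it.

sbsites packages that analysis: site calling from junction reads,
TA/non-TA classification, dinucleotide spectra, and the
position-frequency-matrix (PFM) machinery that exposes the junction
asymmetry and the end correspondence. Because real junction libraries
are bulky and rarely redistributable, the package also owns a
synthetic-data generator that reproduces the statistical structure the
analysis assumes, making every stage testable end to end.

## Junction geometry and orientation conventions

All internal coordinates are 0-based half-open; user-facing tables are
1-based inclusive and say so in their headers.

A junction read is `end + fragment`: the transposon portion of the
read (the sequence between the sequencing primer and the junction),
then genomic DNA starting at the target dinucleotide. For an
integration on the genomic plus strand, the right-side library reads
the plus strand downstream of the target (`fragment` maps `+`), while
the left-side library reads the upstream flank outward, i.e. the
reverse complement (`fragment` maps `-`); a minus-strand integration
mirrors this. The caller therefore takes the target dinucleotide as
the first two bases of the fragment *in read orientation*, from the
reference: `genome[s, s+2)` for a `+` alignment, the reverse
complement of the fragment's last two reference bases for a `-`
alignment. TA is its own reverse complement, so canonical sites read
TA from both sides; a non-TA junction reads non-TA only from its own
side.

Flanking windows are indexed `-W..-1, D1, D2, +1..+W` in sequenced
orientation: `D1 D2` is the target dinucleotide, negative offsets are
junction-proximal (the primer/transposon side), positive offsets
distal. With this convention "the consensus sits opposite the
sequencing primer" becomes simply "information content concentrates at
positive offsets" — in both libraries, each in its own orientation —
which is what `sideBias()` (mean IC over `+1..+L` minus mean IC over
`-L..-1`) measures. `combineSides()` pools the two libraries by
reverse complementing the right-side windows onto the left-side frame,
which doubles the sequence count behind the combined matrix; the
mirror image of the motif then also appears at the proximal positions
of the combined logo, which is expected and harmless for consensus
calling at `+1..+L`.

### End motifs and the mutated-end presets

The registry ships the end sequences as configuration, not constants:
real IR/DR sequences vary by construct, so the presets carry 20-base
synthetic ends whose final four bases are the biologically meaningful
part — the motif adjacent to the junction in read orientation. The
motif in "logo orientation" is the reverse complement of the outermost
four bases of the inverted repeat written 5'→3' outward: the canonical
IR terminus `CAGT...` gives motif `ACTG`. This mapping is validated by
the mutant design: keeping the first (transposition-critical) outer
nucleotide and swapping outer positions 2–3 (`AG→GA`) yields motif
`ATCG`, exactly the consensus recovered from mutated-end libraries.
Applying the same mapping to an A>T transversion at outer position 2
gives the `pYT53` preset motif `ACAG`; since the strand convention of
that published description is ambiguous, the preset motif is explicit
configuration the user may override. For asymmetric constructs
(`pYT21`/`pYT22`, one end mutated) each library is compared against
*its own* side's motif (the last four bases of that side's end), which
is also what the simulator plants; the construct-level `endMotif` (the
left/logo-orientation motif) is used for the combined comparison.

## The synthetic-data generator

The generator defines the study conditions the tests and the
acceptance run measure against; its defaults are fixed, not tuning
knobs.

* **Genome** — i.i.d. bases, GC 0.5, 1 Mb by default; chromosomes are
  resampled (bounded retries) if TA density falls below 1 per 200 bp,
  which the integration model needs. At GC 0.5 the expected TA
  frequency is 1/16 per dinucleotide position, which the tests verify
  against the closed form.
* **Events** — `nEvents = 20000` by default; an event is aberrant with
  `pNonTA = 0.014`, the non-TA frequency reported for large SB
  integration screens. Canonical events are placed at uniformly chosen
  TA sites. Aberrant events choose a side uniformly, a non-TA
  dinucleotide uniformly from the 15 (CG excludable by flag for
  CpG-depleted genomes), and a realized distal pattern in which each
  of the L motif positions matches the side's end motif with
  probability `motifMatchProb = 0.8` and otherwise is a uniformly
  chosen different base; the event is then placed by rejection
  sampling among genomic loci realizing exactly that junction context,
  and errors out, as it should, if a context cannot be found after
  bounded retries. The junction on the other side resolves at the
  nearest unused TA. `motifMatchProb` is a free parameter of the
  generative model — no published estimate exists — and 0.8 was chosen
  once as "strong consensus, visible noise", the regime the published
  logos suggest.
* **Distinct sites** — positions are sampled *without* replacement by
  default (`distinctSites = TRUE`). With replacement, 20,000 events on
  a 1 Mb genome would merge ~1,600 coincident events at deduplication
  and bias the recovered non-TA rate upward by construction; without
  replacement, position-level deduplication removes exactly the PCR
  duplicates and truth recovery is exact. Recurrent integration at a
  shared hot site is a real phenomenon, but conflating it with PCR
  duplication is not something a position-keyed deduplicator can
  resolve, so the generator keeps the two separable.
* **Reads** — `readLength = 60` (20-base end + 40-base fragment),
  constant Q30 qualities, substitution errors i.i.d. at
  `errorRate = 0.001` (Q30-consistent; indels are deliberately absent
  because the analysis is junction-anchored and indel realism
  exercises no additional logic), duplicates per junction
  `1 + Poisson(0.5)` so deduplication has real work. One aberrant
  junction never emits a read pretending to be the other side.

What the generator does *not* emulate: chromatin accessibility and TA
hot-spot preference, local hopping, amplification bias, chimeric
reads, non-uniform genome composition. Passing tests therefore show
that the pipeline's arithmetic, orientation handling and estimators
are correct under the stated model — not that real libraries are free
of those additional effects.

## The internal aligner and its guarantee

`buildKmerIndex()` stores every plus-strand k-mer position (k = 12 by
default, valid range 8–16) in a keyed data.table; minus-strand hits
come from looking up the reverse complement of query k-mers.
`mapFragments()` seeds candidates from all non-overlapping k-mer tiles
of the fragment plus its terminal k-mer, on both strands, extends each
candidate by Hamming comparison over the full fragment, and reports
the best alignment with at most `maxMismatches = 2` mismatches —
`unique` when a single locus wins, `ambiguous` on ties, `unmapped`
otherwise. Tiling gives a pigeonhole guarantee: whenever the true
mismatch count is below `floor(len/k)`, at least one tile is error
free, so the search is equivalent to an exhaustive scan. Pipeline
fragments are 40 bp (three tiles), so the default allowance is fully
covered; the test suite checks equivalence against an independent
exhaustive-scan oracle on 1,000 fragments over a 50 kb genome with a
duplicated block. Ambiguity is a plain tie in mismatch count — no
suboptimal-ratio heuristics — because that rule is oracle-checkable.
There is no indel alignment internally; SAM import accepts indel
CIGARs but derives the junction from POS, since only the junction base
drives the analysis. Post-alignment filtering defaults (unique-only,
fragment ≥ 20 bp) are declared replacements for the unstated filters
of typical insertion-site pipelines, and are all config-exposed.

## Numerical choices

* **Pseudocount 0.1** in PFM frequencies: stabilizes consensus and IC
  at the tens-of-sites scale typical of non-TA sets while being
  invisible at thousands of sites. IC is computed with `0·log 0 = 0`,
  uniform background by default (range then 0–2 bits), optional
  genome-composition background, and an optional Schneider-style
  small-sample correction (off by default; which correction, if any,
  classic logo tools applied is tool-specific).
* **Ties render as `N`** in the consensus and count as mismatches in
  `endMatchScore()`: conservative and deterministic.
* **Windows containing N are excluded** from logo counts (N carries no
  base information); exclusion counts are reported, never silent.
* **Deduplication key** is (chrom, dinucleotide position, strand,
  side); read-level counting is available via `byPosition = FALSE` for
  libraries where duplicates are informative.
* **Non-TA percentage** is reported at 3 decimals in rendered tables;
  accessors return full precision.
* **Degenerate inputs**: empty FASTQ screens to zeroed stats; an empty
  site set tabulates to all-zero counts with proportion `NA`; a
  library with no non-TA sites skips the logo step with a note and the
  run still succeeds.

## Recovering the planted non-TA rate

`pNonTA` is a per-*event* probability, but an aberrant event exposes
its non-TA dinucleotide at exactly one of its two junctions, so each
per-library table shows roughly half the event-level rate. The
pipeline's estimator of the planted rate is therefore pooled non-TA
junctions across both libraries divided by the number of integrations
(the mean of the two library totals). On the default conditions (1 Mb
genome, 20,000 events, error-free reads) the estimate equals the
realized simulation draw exactly, and its 95% binomial confidence
interval covers the planted 1.4% — this is what `scripts/acceptance.R`
recomputes. Problem sizes used by the test suite were chosen as the
smallest that make each property sharp: 50–200 kb genomes and
40–500 events for unit and pattern tests, the full 20,000-event run
for rate recovery, 1,000 fragments for the aligner oracle.

## Known limitations

* The internal aligner targets desk-scale references (tens of Mb at
  most); for mammalian genomes, align externally and enter through the
  SAM door.
* Position-keyed deduplication cannot distinguish independent
  recurrent integrations at one site from PCR duplicates.
* The generator's aberrant model plants the motif with independent
  per-base match probability; real aberrant junctions may have
  correlated mismatch structure.
* Consensus comparison is descriptive (argmax consensus vs motif);
  the package deliberately does not test motif enrichment against a
  genomic background model.
* Logo rendering is a minimal self-contained SVG, not a typographic
  reproduction of classic logo software.
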