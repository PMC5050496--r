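---
title: "Reading-frame fate, diversity and serology statistics for ORFeome phage display"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reading-frame fate, diversity and serology statistics for ORFeome phage display}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orfdisplay)
```

## The problem

ORFeome phage display clones randomly fragmented (meta)genomic DNA upstream
of the M13 pIII gene on a phagemid. Blunt, non-directional cloning means a
fragment enters in either orientation, cut in any phase relative to its
source codons, with any length residue modulo 3 — 18 equally likely
configurations, only one of which (forward, cut on a codon boundary, length
`3n + 1`) reconstitutes a continuous correct-frame fusion
(`enumerate_cloning_configurations()`). Packaging with a pIII-deleted helper
phage makes the insert::pIII fusion the only source of pIII, so clones whose
insert cannot be translated into the fusion yield no infective particles and
are purged. Sequencing the enriched library and classifying each insert's
reading-frame fate is the central analysis this package implements.

## The frame-fate model

For a vector requiring length residue `r` (`vector_frame_model()`, default
`r = 1`), an insert of length `L` is *in frame* iff `L mod 3 == r`.
Scanning walks the insert 5′→3′ one codon at a time from position
`scan_offset + 1`; every codon equal to TAA, TGA or TAG is a stop. Rescue
searches 3′→5′ for the 3′-most ATG at position `p` with

1. `(L − p + 1) mod 3 == r` (translation from `p` rejoins pIII in frame),
2. no stop codon in the frame opened at `p` within the insert
   (strict mode), and
3. for in-frame inserts, `p` in the scanned frame and past the last stop.

Five mutually exclusive categories result; `IN_FRAME_CLEAN`,
`IN_FRAME_RESCUED` and `OUT_FRAME_RESCUED` are *potential ORFs* and their
peptide is translated (standard code; codons containing N give X, and are
never stops or starts — ambiguity handling the assay description leaves
open).

Design points that were genuinely open, and how they were fixed:

* **Scan-frame origin.** Where codon boundaries fall inside the insert
  depends on unpublished vector geometry, so the first scanned codon is a
  parameter (`scan_offset`, default 0: the first insert base opens a codon;
  junction codons spanning vector bases are not scanned).
* **Rescue predicate.** For in-frame inserts the rescuing ATG must sit in
  the scanned frame beyond the last stop; for out-of-frame inserts any
  frame-compatible ATG qualifies. Whether a stop *downstream* of the
  rescuing ATG disqualifies it is not decidable from the assay description;
  the strict interpretation (it does — the start must have the potential to
  initiate translation of an in-frame product) is the default, with
  `rescue_mode = "presence"` as the permissive alternative.
* **Tie-break.** When several ATGs qualify, the 3′-most is reported
  (the direction the rescue search walks); all satisfy the predicate, so
  the choice affects only the reported position and peptide length.
* **Coordinates** are 1-based inclusive throughout. Reverse-orientation
  clones are classified as read: orientation is a property of the clone,
  not recoverable from a single read, and belongs to the simulator.

## Read handling

`trim_config()` describes reads as
`forward anchor + 5′ spacer + insert + 3′ spacer + reverse anchor`. Anchors
(the amplification primers) are located allowing substitutions only
(default budget 1); if the forward anchor is absent the reverse complement
of the read is tried once. The spacers — vector sequence between primer and
insert — are verified base-by-base with a default budget of 0 mismatches:
an indel anywhere in the vector region slides insert bases into the spacer
window and is rejected as `frame_shifted_vector`, since such reads would
corrupt every downstream frame call. Because the true spacer sequences of
the display vector are unpublished, fixed synthetic spacers
(`TGGCCCAG` / `GGTGGA`) are used consistently by the trimmer and the
simulator.

Quality filtering uses the expected error of a read,
`EE = Σ_b 10^(−Q_b/10)`. The operating threshold of 0.1% is interpreted as
a per-base *rate* (`EE / L`, inclusive at equality); tools in this space
have historically thresholded total expected errors instead, so
`mode = "total"` is available. FASTA input carries no qualities and
bypasses the filter (counted separately). Encoding is fixed to Phred+33.

## Diversity statistics

Dereplication is exact-match only (no similarity clustering), at the
nucleotide or peptide level — redundancy is conventionally discussed at the
peptide level while replicate comparisons use unique nucleotide reads, so
the level is an explicit parameter everywhere. Conventions:

* the median copy number of redundant sequences uses the lower midpoint for
  even counts (copy numbers are integers; the reported median stays one);
* replicate overlap partitions the union of unique sequences into the seven
  exclusive Venn regions, with fractions relative to the union — counts
  never weight the overlap, and "shared by a pair" excludes the triple
  region;
* the Shannon effective count is `exp(H)` with natural-log entropy, so it
  equals the category count for uniform abundances and 1 for a single
  category;
* `top_n_share` breaks count ties lexicographically for determinism.

## What the simulator emulates — and what it does not

`synthetic_config()` drives a chain with known ground truth:
i.i.d.-nucleotide genomes at a configurable GC content (default 0.5),
uniform fragmentation with truncated log-normal insert lengths, uniform
orientation, all-or-nothing packaging survival (potential-ORF clones always
survive; others with leakiness ε, default 0), reads with i.i.d.
substitutions at 0.1% and matching constant Phred qualities, a 4% rate of
one-base vector-spacer indels (the share of frame-shifted vector reads such
libraries typically show), and a 500-nt read ceiling. Two length presets
matter:

* the **cloning preset** (default): window 200–1500 bp as checked on a gel,
  `meanlog = log(300)`, `sdlog = 0.45`, pre-enrichment mean ≈ 330 bp;
* the **sequencing-calibrated preset** (`fragment_min = 8`,
  `meanlog = log(150)`, `sdlog = 1.0`): sequenced libraries of this design
  contain inserts down to 8 nt, so the bulk gel window clearly does not
  bound the cloned fragments; this preset reproduces that size range while
  keeping the pre-enrichment mean near 230 bp.

Under the i.i.d. model several library statistics are analytic and serve as
test oracles: length residues are uniform over {0, 1, 2}; the stop-free
probability of `k` scanned codons is `(61/64)^k`; about 28% of out-of-frame
inserts harbour a rescuing ATG. One consequence worth stating plainly:
all-or-nothing survival on potential-ORF status is only *mildly*
length-selective, because the rescue route is nearly length-neutral and
dominates survivors. Mean insert length therefore drops only by ~5–15 nt
upon enrichment in this model, not by the several-fold reduction real
libraries show — real enrichment is additionally biased by
rescue-translation inefficiency, growth and display bias, and amplification
bias, all deliberately collapsed here (panning likewise collapses avidity,
washing stringency and amplification into a single affinity scalar plus
additive background). Passing tests on this generator demonstrate the
*bookkeeping and frame arithmetic* of the pipeline, not compositional
realism: there are no genes, no codon usage, no taxa, and no chimeras.

Panning resamples `phage_per_round` particles each round with weights
`input × (affinity + background)` (multinomial), then samples screened
colonies from the final pool — enrichment of a reactive clone is monotone
in expectation, verified by averaging 100 seeded runs. Random streams are
split per stage (a derived seed per generator), so changing one stage's
draw count does not perturb the others; everything is bit-reproducible
under a fixed seed.

## Serology

ELISA tables carry duplicate peptide wells and one streptavidin-only well
per serum. The corrected response is `mean(duplicates) − streptavidin`,
per mouse — the background is subtracted per individual because
streptavidin reactivity varies between sera; negative corrected values are
retained (the rank test is unaffected) and sera whose background exceeds
the peptide signal are flagged. Cohorts are compared with a two-sided
Mann-Whitney test: exact null distribution when `n1·n2 ≤ 400` with no ties,
otherwise the normal approximation with tie and continuity correction; the
mode used is recorded in the output, and the degenerate all-tied case
returns p = 1. Stars follow the 0.05 / 0.01 / 0.001 thresholds.

## Problem sizes and numerical choices

The test suite works at sizes chosen to make its statistical checks sharp
while staying quick: classifier-versus-oracle agreement on 1,000 random
inserts of ≤ 60 nt; `(61/64)^k` convergence at 10,000 inserts per
`k ∈ {5, 10, 20}` within three binomial standard errors; residue-class
uniformity at 10,000 clones; the enrichment length-direction estimate
pooled over five generator streams of 6,000 clones (the effect is small, so
a single stream's sign is noisy); null super-uniformity of the exact
rank-sum p over 2,000 simulated effect-free datasets at α ∈ {0.01, 0.05};
and panning monotonicity averaged over 100 seeds. `scripts/acceptance.R`
runs the full chain at 20,000 clones. All stochastic assertions use
three-standard-error bands around analytic values — never tuned constants —
and every degenerate input (empty sets, all-zero weights, all-tied samples,
sub-codon inserts) has a defined, tested behaviour.

## Known limitations

* Exact dereplication only; no clustering, rarefaction or chimera handling.
* No homology annotation of selected peptides.
* The classifier trusts its input frame convention; it cannot detect a
  mis-specified `required_residue` from data.
* Sequencing errors are i.i.d. substitutions; indels occur only as the
  modelled vector anomalies.
* The enrichment model reproduces direction, not magnitude, of
  insert-length shifts (see above).
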