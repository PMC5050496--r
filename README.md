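# orfdisplay

Informatics for **ORFeome (functional metaproteome) phage display**: libraries
built by randomly fragmenting (meta)genomic DNA and blunt-cloning the pieces
upstream of the M13 minor coat protein III gene (pIII) on a phagemid. Because
cloning is non-directional, only 1 of 18 equally likely configurations
(2 orientations × 3 cut phases × 3 length residues) yields a continuous
correct-frame oligopeptide::pIII fusion; packaging with a helper phage that
lacks its own pIII gene then strongly enriches clones whose insert still
encodes a translatable fusion. `orfdisplay` implements the sequencing-side
analysis of such libraries and a ground-truthed simulator of their
construction, for people analysing phage-insert amplicon data or planning
such screens.

## The core computation

For an insert of length *L* cloned into a vector requiring length residue
*r* (default *r* = 1, the "3n + 1 rule"), the insert is **in frame** iff
*L* mod 3 = *r*. Each insert is scanned codon-by-codon from its 5′ end for
stop codons (TAA, TGA, TAG), and searched from the 3′ end for the 3′-most
alternative start codon (ATG) at a position *p* satisfying

* (*L* − *p* + 1) mod 3 = *r* — translation from *p* rejoins pIII in frame,
* no stop codon in the frame opened at *p* (strict mode), and
* for in-frame inserts, *p* in the scanned frame downstream of the last stop.

This yields five reading-frame fates — `IN_FRAME_CLEAN`, `IN_FRAME_RESCUED`,
`IN_FRAME_DEAD`, `OUT_FRAME_RESCUED`, `OUT_FRAME_DEAD` — of which the first,
second and fourth carry a potential oligopeptide::pIII gene product. Around
the classifier sit: vector-flank trimming with frame-integrity checks,
expected-error read filtering (Σ 10^(−Q/10) per base), dereplication /
redundancy / replicate-Venn / Shannon-effective diversity statistics, a
biopanning enrichment simulator, and background-subtracted Mann-Whitney
serology comparisons.

## Worked example

```r
library(orfdisplay)

classify_insert("TAAATGGCAA", id = "ex1")
#> Frame report [ex1]: 10 nt, R1, IN_FRAME_RESCUED
#>   stop codons at: 1
#>   rescuing start at: 4
#>   peptide: MA
```

The 10-nt insert is in frame (10 mod 3 = 1) but opens on a stop codon; the
ATG at position 4 rejoins the vector frame ((10 − 4 + 1) mod 3 = 1) with no
downstream stop, so the clone is rescued and displays the dipeptide MA.

A full simulated run — library construction, strict ORF enrichment,
sequencing, trimming and profiling:

```r
cfg <- synthetic_config(n_clones = 2000, seed = 42)
run <- simulate_library(cfg)
trimmed <- trim_reads(run$reads, trim_config())
profile_library(classify_inserts(trimmed$inserts))
#> ORFeome library profile (367 inserts )
#>   residue classes  : R0 32.7%  R1 32.4%  R2 34.9%
#>   categories       : IN_FRAME_CLEAN 6  IN_FRAME_RESCUED 113  IN_FRAME_DEAD 0  OUT_FRAME_RESCUED 246  OUT_FRAME_DEAD 2
#>   potential ORFs   : 99.5%
#>   in-frame rescues : 100.0% of stop-carrying in-frame inserts
#>   insert length    : mean 307.9 nt (range 200-447)
```

With leak-free enrichment nearly every surviving, successfully trimmed
insert carries a potential ORF; the two `OUT_FRAME_DEAD` inserts are
sequencing-error artefacts (the simulator's 0.1% substitution rate can
destroy a rescuing ATG). Reads longer than the 500-nt ceiling lose their
3′ anchor and are excluded at trimming, capping observed inserts at 447 nt.

Serology of two cohorts, with per-mouse streptavidin background subtraction:

```r
compare_cohorts(simulate_serology(10, 10, effect = 0.4, seed = 7))
#>   peptide_id statistic      p_value median_case median_control stars
#> 1  peptide_1       100 1.082509e-05   0.3735369     0.07291732   ***
```

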