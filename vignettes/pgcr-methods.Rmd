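---
title: "Calling and characterising Progestin Control Regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and characterising Progestin Control Regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgcrtools)
library(GenomicRanges)
```

## The biological question and the model

Steroid-hormone receptors rarely regulate genes from proximal promoters.
In hormone-responsive endometrial cells, progesterone-receptor (PR)
binding sites cluster in distal regulatory neighbourhoods that also
recruit the pioneer-like factor PAX2, and these neighbourhoods sit inside
topologically associating domains (TADs) together with the genes they
control. `pgcrtools` implements a rule-based caller for such
neighbourhoods — *Progestin Control Regions* (PgCRs) — and the battery of
analyses used to characterise them.

A PgCR is defined by three conditions, applied in order:

1. **Clustering.** At least `min_pr_peaks` (default 2) PR ChIP-seq peaks
   in which every consecutive edge-to-edge gap is at most `max_gap`
   (default 25 kb). Clusters are the maximal runs satisfying the gap
   rule, so calling is deterministic and order-independent.
2. **Co-factor support.** The cluster span (first member start to last
   member end) overlaps at least one PAX2 peak by one or more bases.
3. **TAD containment.** The span lies entirely within a single TAD.
   Clusters crossing a TAD border are removed: borders behave as
   regulatory barriers, and containment is also what makes the region's
   TAD assignment well-defined.

The span is reported as called; a 1.5 kb flank on each side is attached
only for coverage plotting and export, never for calling.

Two readings of the rule are not fixed by its verbal form, and both are
implemented as options with documented defaults: gaps are measured
edge-to-edge (`gap_mode = "edge"`; summit-to-summit is available), and
PAX2 support is tested against the bare span (`pax_mode = "span"`;
`"flanked"` tests the span ± flank). PR input defaults to whatever peak
set the user supplies; in the motivating system the estrogen-pretreated
PR peak set is the one that satisfies the rule most often.

## Coordinate conventions

All genomic intervals are held as `GenomicRanges::GRanges` (1-based,
closed), the Bioconductor norm; BED and narrowPeak input is converted at
the I/O boundary by `rtracklayer`, so the base sets and overlap
semantics are identical to the 0-based half-open convention of the BED
ecosystem. In particular, abutting intervals (`[100,200)` and
`[200,300)` in BED terms) do not overlap, which the tests assert
explicitly. narrowPeak q-value columns (−log10) are converted to raw
probabilities on read, so all filters use a single unit
(`filter_q(peaks, 1e-5)` reproduces the usual post-calling peak filter).
Summits are stored as 0-based offsets from the interval start, exactly as
narrowPeak column 10 records them.

## Interval statistics

`fisher_association()` builds the 2×2 contingency used by interval
association testing: overlapping A intervals, non-overlapping A, non-
overlapping B, and remaining "slots", computed as
`round(G / (mean(width A) + mean(width B)))` minus the other three cells.
The slot denominator uses the *sum* of the two mean widths because two
intervals of lengths `lA` and `lB` placed uniformly on a genome of length
`G` overlap with probability ≈ `(lA + lB) / G`; with this construction
the test is calibrated (≤ 7% rejections at α = 0.05 under an
independence null, asserted over 200 seeds), whereas dividing by a single
mean width doubles the effective expectation and makes the test
anti-conservative. `shuffle_intervals()` provides the matching
randomisation (length-preserving, chromosome-preserving, non-overlapping,
seeded).

Feature annotation assigns each peak one category by summit position
with fixed priority — promoter (TSS −1 kb…+100 bp, strand-aware) > 5′UTR
> 3′UTR > exon > first intron > other intron > downstream (≤ 1 kb) >
proximal intergenic (≤ 50 kb) > distal intergenic. The annotator the
original analyses used is not specified anywhere; this priority list is
chosen to reproduce the reported category vocabulary ("introns other
than the first intron", "distal > 50 kb") and is documented rather than
claimed canonical.

## Gene association and regulation

`build_regulatory_domains()` implements the basal-plus-extension rule:
a strand-aware basal domain of 5 kb upstream / 1 kb downstream of each
TSS, extended up to 100 kb per side but stopping at the nearest
neighbouring basal domain, so domains only overlap where basal domains
themselves do. Peaks associate to a gene when the peak midpoint falls in
its domain (the cited web tool's convention; any-overlap is an option).

`classify_regulated()` is a pure threshold function: induced iff
`log2FC ≥ 0.8` and `q < 0.05`, repressed iff `log2FC ≤ −0.8` and
`q < 0.05`. The fold threshold is inclusive — "set at log2FC = ±0.8"
places the boundary value inside the regulated class — while the q
threshold is exclusive.

`distance_fc_analysis()` measures, for each regulated gene, the signed
genomic distance from its TSS to the nearest PgCR midpoint (negative
when the TSS coordinate is below the midpoint; the sign is a single
genomic axis, not per-gene strand, which is offered as an option),
splits at 1 Mb into *close* and *far*, and compares absolute
fold-changes with Welch's unequal-variance t-test.

`bootstrap_intersection()` draws `n` genes without replacement from an
explicit universe, intersects each draw with a target list, and reports
the null mean, nearest-rank 2.5/97.5 percentiles (integer endpoints by
construction) and a +1-smoothed two-sided empirical p. The null mean
estimates the hypergeometric expectation `n·K/N`; tests verify agreement
within 3 standard errors over 20 random configurations. The universe is
an explicit argument because published summaries of such tests rarely
print `N`; for a full-scale run we use 19,955, the GENCODE v38
protein-coding gene count, and report `N` alongside the results.

## Hi-C statistics

`ContactMatrix` is a dense symmetric per-chromosome matrix at fixed bin
size (20 kb default, 5 kb for locus-level views). The toolkit provides:

* `depth_normalize()` — scale to a fixed total (10^6); enrichment
  statistics are invariant to this.
* `smooth_focal()` — k×k box average with edge-shrunk kernels,
  symmetry-preserving.
* `virtual_4c()` — a bait-bin row over a region scaled to per-mille
  (sums to 1,000). The bait self-bin is excluded from the normalisation
  sum by default because self-ligation dominates it; `include_self`
  restores plain row scaling.
* `compartment_eigenvector()` — first eigenvector of the Pearson
  correlation of the distance-normalised (observed/expected) matrix,
  sign-oriented by a user track (gene density) so A-like bins score
  positive. The underlying study does not state its compartment
  algorithm; this is the standard correlation-matrix approach and is
  labelled as such. TAD labels are the sign of the mean score over the
  TAD's bins.
* `intra_tad_enrichment()` — bins are labelled PgCR / TSS / other (PgCR
  wins when a bin holds both, as the rarer, analysis-central class);
  the expected contact per distance is the mean over *intra-TAD* pairs
  only, and each class pair's statistic is `log2(Σobs/Σexp)`. Pairs
  crossing TAD borders never contribute. Because planted or real loops
  also enter the background fit, the statistic carries a small downward
  bias (visible in simulations as ≈ 0.92–0.96 recovered for a planted
  log2 enrichment of 1); this is inherent to defining the background
  from all intra-TAD pairs and is left as the method defines it.

## Motif scanning

PWMs are log2-odds matrices with pseudocount 0.01 against an explicit
background, discretised on a 0.01-bit grid. The score distribution under
the background is computed *exactly* by dynamic programming over
positions, and the scan threshold is the smallest grid score whose
survival probability is ≤ the requested p-value (10^-4 by default) —
verified against exhaustive enumeration of all words up to motif length
8. Scanning reports every window reaching the threshold on either
strand; enrichment between two region sets counts regions with ≥ 1 match
(duplicates within a region count once), applies +0.5-count smoothing to
the fractions, tests each motif with Fisher's exact test and adjusts
across the library with Benjamini–Hochberg. A uniform PWM is the
documented degenerate case: every word scores identically, the threshold
is `+Inf`, and nothing matches below p = 1.

## The synthetic-data generator

Every downstream stage is testable offline against
generators whose defaults encode the study conditions: a ~121 Mb genome
(4 chromosomes), 121 TADs averaging ~1 Mb, 121 planted PgCR-like regions
with spans uniform on 10–40 kb (mean 25 kb), Hi-C bins of 20 kb with
power-law decay `scale·(1+d)^-1`, Poisson counts and a loop boost of 2 on
planted region–promoter pairs, and expression effects (|log2FC| mean 1,
σ = 0.3) confined to genes within 1 Mb of a planted region. Each entity
type (genome, TADs, regions, each peak set, matrix, genes, expression)
draws from its own RNG stream derived from the master seed, so identical
configs are bitwise-identical and adding peaks never perturbs the
matrix.

Two generator properties are deliberate:

* `sim_pgcr_scenario()` places background PR peaks pairwise more than
  `max_gap` apart and away from planted regions, so no background run
  can satisfy the two-peak rule — the caller's sensitivity is exactly 1
  and its false-discovery rate exactly 0 on this output. That makes
  recovery a sharp correctness check of the caller, not a statistical
  benchmark.
* `sim_peaks()` makes the co-localised PAX2 count exact: the requested
  fraction of PR peaks receive a PAX2 peak within `colocal_dist`, and
  the remaining PAX2 background is placed conditional on staying
  farther away.

What the generator does **not** emulate: read-level noise, peak-calling
artefacts, copy-number and mappability biases in Hi-C, negative-binomial
overdispersion of contacts (Poisson is the simplest model exercising the
observed/expected statistic), and correlated expression changes. Passing
tests therefore demonstrate algorithmic correctness under the stated
statistical structure, not robustness to every property of real
sequencing data.

On the scaled genome one consequence is worth noting: with 121 regions
on 121 Mb, nearly every simulated gene lies within 1 Mb of a region, so
the close/far fold-change comparison is exercised on sparser
configurations (few regions on larger-per-region genomes) where both
groups are populated.

## Numerical choices

* Tie-breaks: nearest-interval ties go to the lower-coordinate interval;
  `which.min` semantics make this deterministic.
* Percentiles: nearest-rank on the sorted draws, hence integer CI
  endpoints for integer statistics.
* Degenerate inputs are errors or sentinels, never silent: zero-margin
  contingency tables return p = 1 with a warning, empty chromosomes get
  an `Inf` nearest-distance sentinel, all-zero bait rows and constant
  matrices are errors, peaks on chromosomes missing from the gene model
  fall to `distal_intergenic` with a warning.
* Problem sizes in tests and the acceptance script (121-region
  scenarios, 10,000-draw bootstraps, 200-bin matrices, 200-seed
  calibrations) were chosen so the whole battery runs in a few minutes
  on a single core while keeping Monte-Carlo error well below the
  assertion tolerances.

## Limitations

The caller implements a fixed published rule; it does not learn
parameters, call TADs, or use chromatin openness (openness is an
observation about PgCRs, not part of their definition). Compartment
calls at full scale depend on normalisation choices out of scope here
(only depth scaling is provided; bias correction is assumed done
upstream). The bootstrap's null mean depends on the universe size, which
must be supplied explicitly — published values can only be matched to
the extent the original universe is known.
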