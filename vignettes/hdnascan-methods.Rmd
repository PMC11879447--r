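---
title: "hdnascan: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hdnascan: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdnascan)
```

## Scope and coordinates

`hdnascan` detects mirror repeats and their triplex-forming (H-DNA)
subset in genome sequences and quantifies their distribution across
annotated compartments, gene anchors and peak sets. All coordinates are
0-based half-open (`[start, end)`, the BED convention) everywhere inside
the package; GFF3 input (1-based inclusive) is converted at the boundary.
A single convention removes the most common class of off-by-one errors in
interval work. Chromosome names are matched as exact strings — no "chr"
prefix normalization is attempted.

## The mirror-repeat model

A mirror repeat consists of two arms that read identically outward from a
center of symmetry on the same strand, separated by a short unconstrained
spacer. `scan_mirror_repeats()` enumerates every center boundary *p* and
every spacer length *s* in `0..max_spacer` and extends the arms to the
maximal *k* with `seq[p-1-i] == seq[p+s+i]` for all `i < k`. Matching is
case-insensitive (soft-masked lowercase sequence is treated like its
uppercase form), extension stops at any non-ACGT character or sequence
edge, and any motif whose span contains a non-ACGT character is discarded
outright — ambiguity codes never match anything.

Reporting convention: **one repeat per (center, spacer) at maximal arm**.
Nested shorter arms at the same center are not re-reported; overlapping
repeats from *different* centers or spacers are all reported. This is why
the motif count exceeds the merged-region count in repetitive sequence,
and both numbers are always reported side by side. Annotation tools for
non-B DNA differ in exactly this convention (sub-repeat enumeration,
overlap deduplication), so genome-wide raw counts are convention-sensitive;
coverage-based quantities (merged regions, bp densities) are far more
stable and are the package's preferred currency.

Two further modeling decisions, both documented here because the
alternatives are defensible:

* **Composition over the whole motif.** The H-DNA filter (purity
  `max(f_AG, f_CT) >= 0.90`, AT exclusion `f_AT < 0.80`) is computed over
  arms *plus* spacer. A spacer of at most 7 bp cannot move a ≥ 21 bp
  motif across the 90% threshold by more than about one letter, and the
  filter is applied to sequences, not arms.
* **Inclusive thresholds.** Purity passes at exactly 0.90; AT content
  fails at exactly 0.80. The spacer itself is not required to be
  asymmetric — symmetric spacers simply show up as larger arms at the
  same center.

The filter is strand-symmetric by construction: AG-rich on one strand is
CT-rich on the other, and taking the max of the two fractions makes the
H-DNA set invariant under reverse complementation (up to coordinate
reflection). The test suite checks this property directly.

`oracle_scan()` is a deliberately naive second implementation (each
candidate arm length re-verified from scratch by direct character
comparison) kept in the package as the reference the fast scanner is
tested against; it refuses inputs over 5 kb.

## Density, binning and enrichment

* `region_density()` measures merged-motif bp per region bp (reported per
  kB) and merged motif regions per Mb. Merged regions are the density
  currency because they are invariant to the reporting convention above.
  Two folds are reported: `fold_vs_genome`, the region's density over the
  genome-wide density (equivalently, its share of motif bp over its share
  of the genome — the form usually quoted in publications), and
  `fold_vs_background`, density inside over density outside. For a region
  occupying fraction *f* of the genome with a true density ratio *R*
  against the background, `fold_vs_genome = R / (1 + (R-1)f)`; the two
  agree only as *f* → 0, and `fold_vs_background` is the one that
  recovers a planted ratio exactly.
* `assign_bins()` uses `bin(x) = 1 + floor(n_bins·x/chrom_size)` on start
  and end coordinates and counts multi-bin motifs in every intermediate
  bin. `bin(chrom_size)` would be `n_bins + 1`; since `end = chrom_size`
  is legal under half-open coordinates it is clamped into the last bin.
* `fisher_overlap_test()` works at the site level ({sites in region,
  sites outside} × {≥ 1 motif overlap, none}); the p-value is the exact
  two-sided hypergeometric probability from `fisher.test`, and the
  reported odds ratio is the sample cross-product ratio with 0/∞ flagged
  rather than the conditional-MLE estimate.
* `bootstrap_quantiles()` resamples sampling units (anchors, peaks) with
  replacement, N = 1000 by default, and reports the empirical 0.025 and
  0.975 quantiles per position — a 95% interval. The lower quantile is
  0.025 by design (a "0.25" lower end alongside a 0.975 upper end would
  not be an interval of any standard coverage). A seed is mandatory and
  the caller's RNG state is restored.

## Positional profiles

`site_profile()` counts motif *base pairs* (not motif starts) at each
signed offset around anchors, after consolidating the motif set so each
genomic base counts once per anchor; minus-strand anchors flip the offset
sign so downstream is always positive. Enrichment is the count over the
window mean, so a flat profile sits at 1. Anchors within a half-window of
a chromosome edge contribute their in-bounds offsets rather than being
dropped (the alternative discards exactly the anchors that are often of
most interest near short contigs). Peak anchors are floor-midpoints of
their intervals. `rdna_bin_profile()` applies the same binning rule along
each array span (3500 bins by default) and reports both count/mean
enrichment and each bin's share of the array total, with rRNA genic
intervals overlaid as bin ranges. Profiles anchored on rRNA genes use the
18S and 28S records; 5.8S is overlay-only.

`filter_and_merge_peaks()` applies the FDR filter strictly (`q < 0.005`;
a peak at exactly the threshold is dropped) before consolidation, and
`max_enrichment_class()` classifies a profile by whether its maximum
enrichment falls within 250 bp of the anchor, breaking exact ties toward
the smallest |offset|.

Interval consolidation everywhere merges bookended intervals
(`[1,5)` + `[5,9)` → `[1,9)`), matching the default of the standard BED
merge utility; merged-region counts shift by a handful under the opposite
convention, which is one more reason to prefer bp-coverage measures.

## The synthetic study conditions

`synthetic_spec()` defaults define the conditions every end-to-end test
runs under:

| parameter | default | why |
|---|---|---|
| genome_len | 10 Mb | large enough for stable densities, scans in seconds |
| gc | 0.41 | human-like background composition |
| arrays | 5 × (20 × 5 kb units) | tandem rDNA-like arrays, 0.5% of the genome |
| genic layout | 18S/5.8S/28S placeholders per unit | IGS-restricted planting is measurable against genic bins |
| planted motif | `ctctctctgt` + `c` + reversal | the modal CT-rich rDNA motif family (arm 10, spacer 1) |
| IGS plantings | 4 per unit at fixed offsets | periodic signal along the array |
| background rate | 20 motifs/Mb | array/background bp-density ratio of exactly 40 |
| negative classes | 30 mirror-only + 30 decoys | filter specificity is scored, not assumed |

Planted motifs are flanked by fixed breaker bases so their arms cannot
extend into the background, which makes exact-coordinate recovery a
well-defined target. After assembly the genome is rescanned and any
accidental background H-DNA is redrawn locally (flanks only; planted
spans and array sequence are never touched), so the truth ledger is
exhaustive for the H-DNA class at this scale. Classes are verified at
generation time: every `hdna` row passes the compositional filter, every
`mirror_only` row is a mirror repeat that fails it, and decoy templates
contain no qualifying mirror at all.

What the generator does *not* emulate: mutational degradation of repeat
units (arrays are exact copies), interspersed repeat families, centromeric
satellite structure, chromosome-scale GC variation, and soft-masking
patterns of real assemblies. Passing recovery and enrichment tests on
these conditions therefore demonstrates correctness of the machinery —
scanning, interval algebra, normalization, resampling — not scanner
robustness to the full messiness of a real assembly, where reporting
conventions of other tools and annotation quality dominate the residual
uncertainty.

## Problem sizes and numerical choices

The test suite and the acceptance script use: scanner–oracle equivalence
on ~100 random sequences of 500–2000 bp across three parameter settings;
recovery, enrichment and profile checks on the 10 Mb default genome;
bootstrap calibration with 500 replicates of 30 Gaussian units at
N = 1000 (a deliberate small-sample regime where bootstrap percentile
intervals are expected to sit a point or two below nominal coverage);
and a 1000-anchor null profile binned at 300 bp so that every bin holds
several motif events in expectation — bins with no observed event have a
degenerate resampling distribution and cannot speak to flatness. Since
pointwise 95% bands miss the null value for ~5% of bins by construction,
the flatness criterion asks that at least 90% of bins cover 1.

Degenerate inputs follow one rule: undefined ratios (zero-bp regions,
zero window means, zero genome fractions, all-zero contingency tables)
return flagged `NA` values with a warning rather than errors, while
structurally invalid inputs (motifs outside the chromosome, empty array
tracks, missing seeds, missing q-value columns) raise errors naming the
offending element.

## Limitations

* Arms must mirror exactly; mismatch-tolerant arms and thermodynamic
  triplex stability scoring are out of scope.
* The STR scanner is a transparent exact-tandem definition (primitive
  unit ≤ 9 bp, ≥ 2 full copies, no mismatches); dedicated tandem-repeat
  finders with mismatch models will report different coverage, which
  shifts STR-overlap percentages on real data.
* G4 calling uses the run-scoring scheme with its published defaults
  (window 25, mean |score| ≥ 1.5); overlap figures involving G4s are
  sensitive to both.
* Genome-wide *raw* motif counts depend on the reporting convention noted
  above; cross-tool comparisons should be made on merged regions or bp
  coverage.
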