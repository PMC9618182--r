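---
title: "Methods: pooled-cohort synaptic proteome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled-cohort synaptic proteome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synaptomics)
```

## The analytical problem

Synaptoneurosome preparations — resealed presynaptic terminals with
attached postsynaptic spines — let deep proteomics reach the synaptic
compartment of human post-mortem cortex. When donors are pooled into one
representative master sample per experimental group and all groups are
quantified together in a single TMT 10-plex LC–MS/MS run, the resulting
data are one reporter-intensity column per pool with no within-group
replication. Classical per-protein significance testing is therefore
unavailable by design; the analysis instead rests on ratiometric values
between pools, a loading correction, and a biologically motivated
fold-change criterion, followed by set logic across the stratified
comparisons, annotation, and over-representation analysis. This package
implements that workflow end to end, together with seeded synthetic
generators so that every stage is testable without any external data.

## Design and data model

The default design (`pool_design()`) is ten pools over two cortical
regions — primary motor cortex (BA4) and dorsolateral prefrontal cortex
(BA9) — giving eight case/control comparisons: whole-group disease vs
control per region, cognitive strata (ALSnoci / ALSci) vs control per
region, and C9ORF72-repeat-expansion strata (C9neg / C9pos) vs control
in BA9. A protein quantification table is one row per protein group:
accession (the primary key; gene symbols are annotation only, since
symbols collide), a unique-peptide count, and one positive intensity per
pool, with zero and blank cells treated as "not detected". Missingness
is evaluated on the raw table, before any transformation, because
search-engine exports encode non-detection as either zeros or blanks and
both mean the same thing.

## Filtering

Two clean-up rules produce the analysis-ready table
(`filter_analysis_ready()`): proteins must be identified by at least two
unique peptides, and must be detected in every pool. The filter is
idempotent and order-independent; its report attributes a row failing
both rules to both counters and reconciles totals through the union of
failing rows, so `n_input = n_retained + |failing union|` always holds.

## Ratiometric values, loading correction and classification

For each comparison the raw ratio is case-pool intensity over
control-pool intensity. Small differences in the amount of material
labelled per channel shift all ratios of a comparison by a common
multiplicative factor, so every ratio is divided by the per-comparison
median over all analysis-ready proteins ("1/median" normalization); the
median normalized ratio of every comparison is then exactly 1, which is
asserted to `1e-12` at run time. The median is computed within each
comparison rather than globally because loading differs per pool. The
correction makes normalized ratios invariant to any rescaling of a
pool's intensities, which the suite checks as a property.

A protein is called UP when its normalized ratio is at least 1.2 and
DOWN when at most 0.8, both bounds inclusive — a 20% change, the level
that orthogonal quantification (quantitative immunoblotting) can
confirm. The threshold is applied after the 1/median step, since the
loading correction is part of producing the ratiometric value, not of
interpreting it. Note the pair 1.2/0.8 is deliberately not reciprocal:
1/1.2 ≈ 0.833 is not DOWN. The suite asserts this documented asymmetry
rather than "fixing" it, because the criterion is a symmetric absolute
change of ±20%, not a symmetric log-ratio.

For display, log2 ratios are standardized per protein row across the
groups shown (z = (value − row mean)/row sample SD); rows with zero
spread cannot be standardized and are returned as zeros with a
degenerate flag. Row ordering uses agglomerative clustering on Euclidean
distance with complete linkage (the default of the common heatmap
tools; configurable).

## Set logic and specificity

`altered_sets()` collects UP/DOWN/altered accession sets per comparison.
A protein is *specific* to a target comparison relative to an explicit
contrast group when it is altered there and not altered in any listed
other comparison; specific and shared subsets always partition the
target's altered set, an identity re-asserted inside the pipeline. The
contrast group is an explicit argument, never inferred: for cognitive
strata, for instance, one may subtract only the same-region non-impaired
comparison or also the cross-region one, and that is an analytical
choice the caller must make. Venn regions (2–4 sets) are counted by
membership enumeration and checked against a brute-force oracle;
rankings (`top_k()`) break ties lexicographically by accession so
results are deterministic.

## Annotation

Reference proteome/synapse lists and pre/postsynaptic compartment maps
are plain TSV. Identifier normalization is deliberately mild:
case-insensitive symbols, isoform suffixes stripped from accessions.
`overlap_fraction()` is directional — the dataset is always the
denominator — and `compartment_distribution()` conserves counts, with
unmapped identifiers reported as `unknown` rather than dropped. The
shipped reference files are synthetic illustrations; real use should
point at the published resources, whose exact release determines the
overlap numbers.

## Over-representation analysis

The enrichment computation the common web tools perform is implemented
in-repo so runs are reproducible offline: for a query of size *n* drawn
from a universe of size *N* containing *K* members of a set, the p-value
is the upper hypergeometric tail P(X ≥ k) and fold enrichment is
(k/n)/(K/N). The universe is the intersection of the analysis-ready
proteins with the collection's annotation space — the background a web
tool uses when given a custom list — which avoids inflating enrichment
with unannotatable identifiers. The test is one-sided
(over-representation only) and Benjamini–Hochberg FDR is attached within
each collection, not across collections. Against exact enumeration the
p-values agree to `1e-12` for universes up to N = 25, and over 10,000
uniform null queries the empirical type-I error at p ≤ 0.05 stays below
0.05 (the discrete test is conservative).

## Validation statistics

Two small computations support validation. First, ordinary least squares
of orthogonal-method ratios (band intensity over total-protein stain,
case over control) on proteomics ratios, with R² the squared Pearson
correlation and a two-sided zero-slope p-value; R² is invariant to
affine rescaling of either axis. Second, a two-sample t-test computed
purely from group means, SDs and sizes, for contrasts where only
summary demographics are available (e.g. cognitive screen totals of
impaired vs non-impaired strata). Student's pooled-variance form is the
default — with rounded summary inputs the choice cannot be recovered
from a printed p-value — and Welch is available by flag; both reproduce
a raw-data `t.test()` to `1e-10` when fed a sample's own summaries.

## Array tomography

Serial 70 nm sections give single-synapse resolution; synaptic markers
appear as small punctate objects, and a postsynaptic punctum belonging
to the same synapse as a presynaptic punctum sits directly opposed to
it rather than on top of it. The imaging module thresholds each slice
at its own mean + k·SD (per-slice, because staining varies section to
section; k defaults to 2 and is explicit configuration — noisy stacks
warrant a larger k, as the analysis driver illustrates with k = 4),
labels the binary volume with 3D 26-connectivity across sections, and
discards components outside configurable voxel-count and slice-span
bounds. Centroids and all distances are physical (nm), respecting the
anisotropic voxel size. Colocalization is centroid-distance based — a
channel-B punctum counts as colocalized when some channel-A centroid
lies within 500 nm (configurable) — reflecting "opposed", not
"overlapping", marker pairs. Densities are puncta per µm³ of analyzed
volume, and group differences are expressed as percent change of group
means. Stack alignment is assumed done upstream.

## Synthetic generators

The cohort generator draws baseline intensities log-normally (log10
mean 6, sd 0.5) to mimic the reporter-intensity scale — the exact values
are immaterial because everything downstream is ratiometric — applies
planted fold changes to case pools before noise, then independent
multiplicative log-normal noise of configured CV to every cell. Default
conditions describe the cohort the workflow is built for: 6000 proteins,
10 pools, 8 comparisons; 6% of proteins altered per comparison, split
evenly UP/DOWN with fold changes in 1.3–2.5 and 0.4–0.77 (clearly beyond
the thresholds, as observed changes are); 8% single-peptide rows and 4%
of proteins given one missing value in a non-control pool, so the two
filters together remove roughly 700 of 6000; noise CV 5%, appropriate
for pooled samples where biological variance has been averaged out.
Missing values go only to non-control pools by default so every ratio
has a denominator. All randomness flows from a single seed, and
identical seeds give byte-identical output.

The image generator plants 2×2×2-voxel blobs with at least two empty
voxels between same-channel footprints (so components can never merge
under 26-connectivity), places a configured fraction of channel-B
puncta within a 300 nm opposition distance of a channel-A punctum and
the rest uniformly at random away from any A punctum, then optionally
applies separable Gaussian PSF blurring and additive noise. On
noiseless stacks segmentation recovers planted counts exactly and
centroids to within one voxel, and the measured colocalization fraction
equals the planted one to within one punctum.

What the generators do *not* emulate bounds what green tests show about
real data: no peptide-level quantification or reporter-ion
interference, no correlated protein covariance or batch structure, no
isoform ambiguity, and blob-shaped puncta rather than realistic PSFs
over irregular synapse morphologies. Passing tests demonstrate the
computations are correct and calibrated under the stated statistical
structure, not that any particular biological conclusion transfers.

## Numerical choices and degenerate inputs

Medians use R's default (mean of central order statistics for even n);
z-scores use the sample SD (n − 1); classification bounds are inclusive;
ranking ties break by accession; a single p-value is its own BH
adjustment; two zero-variance groups with equal means give t = 0, p = 1
with a degeneracy flag; empty puncta lists give colocalization 0; and
segmentation uses a strict `>` against the slice threshold so an
all-zero slice yields an empty mask. Problem sizes in the test-suite
and acceptance runs (500–6000-protein cohorts, 10,000-query null
calibration, 64×64×12 stacks) were chosen as the smallest at which the
stochastic properties are stable.

## Pipeline and reproducibility

`validate_config()` collects *all* configuration problems before
failing, and `run_pipeline()` re-asserts the internal identities
(median-1 normalization, specificity partition) as it runs, writes TSV
tables and a JSON report when an output directory is set, and is
bit-identical across reruns of the same config and seed on synthetic
input. The numbered scripts under `analysis/` narrate the workflow
stage by stage on a simulated cohort; `scripts/acceptance.R` recomputes
the headline quantities from scratch.

## Known limitations

Pooling trades inferential power for robustness: with one master sample
per group there is no per-protein variance estimate, and the ±20%
criterion is a practical, validation-driven cut, not a significance
statement. Specificity logic is sensitive to the chosen contrast group.
Enrichment results depend on the annotation collection and universe;
within-collection FDR does not correct across collections. The imaging
thresholds (k, size bounds, colocalization radius) are explicit
configuration with sensible defaults, not estimated from data.
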