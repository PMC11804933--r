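---
title: "Models and methods behind rbpduet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rbpduet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbpduet)
```

rbpduet analyzes the joint behaviour of two RNA-binding proteins (RBPs)
profiled by iCLIP across developmental stages, the situation created by
opposing temporal regulators in neural stem cell lineages: one RBP high
early, the other high late, with a shared mid stage where both are present.
This vignette explains each model, the tunable parameters and their
defaults, the numerical decisions, what the synthetic-data generators do and
do not emulate, and the package's known limitations. Coordinates are 0-based
half-open everywhere internally (the BED convention); 1-based inputs must be
converted at the boundary, and interval statistics are computed in
transcript coordinate space, with genomic-space sites projected through a
`transcript_annotation` first.

## Expression-normalized occupancy and temporal clustering

iCLIP read counts at a gene confound binding strength with transcript
abundance, so the occupancy score divides out expression:

1. **Background subtraction** (`subtract_background`): the mean count over
   nonsignificant positions (cross-link FDR > 0.01 in the upstream caller)
   is subtracted from each significant position, clamped at zero. The
   background is computed per gene, not globally, because nonspecific
   cross-linking scales with local coverage.
2. **Scoring** (`iclip_score`): corrected significant reads are converted to
   reads per million of the library and divided by the gene's TPM
   (floored at 0.1 to avoid division blow-ups). Scores are computed per
   replicate and averaged (`occupancy_matrix`); a pseudo-count of 0.5× the
   smallest non-zero score is carried on the object for plotting/export of
   signal-free genes but never enters any statistic.
3. **Profile filtering**: per gene, a quadratic regression over stage
   pseudo-time with an RBP series intercept is fitted under a
   negative-binomial observation model with fixed dispersion θ = 10. The
   fit uses the background-corrected read counts with a
   log(library size × TPM) offset — the count-scale formulation of the
   normalized score, which keeps the likelihood honest (NB likelihoods are
   meaningless on small normalized ratios). Genes are retained when the
   profile-versus-flat likelihood-ratio test passes Q ≤ 0.01 after
   Benjamini–Hochberg adjustment across genes and the deviance R² is at
   least 0.7. The thresholds (Q = 0.01, θ = 10, R² = 0.7, k = 6) are the
   conventional ones for this analysis. The time-course regression is a
   deliberately simple stand-in for a full time-course DE framework: with
   two series over three stages there are only four library conditions, so
   any richer design is saturated anyway; what matters — and what the tests
   check — is that structured profiles pass and flat profiles are removed.
   Whether "Q" should be BH-adjusted is genuinely open; BH is used because
   an unadjusted 0.01 across hundreds of genes would not control anything.
4. **Clustering**: retained aggregated profiles are z-scored per gene over
   libraries and clustered by Ward agglomeration (`ward.D2`, Euclidean) cut
   at k = 6. Cluster ids are renumbered by descending centroid
   RBP1-minus-RBP2 contrast so the numbering is reproducible.
   `assign_groups` then names each cluster: strict maximum (minimum) of the
   centroid at the partner RBP's shared mid-stage library gives
   `peak_mid_rbp2` (`reduced_mid_rbp2`), these taking precedence; otherwise
   the sign of the RBP1-vs-RBP2 centroid contrast decides, with a
   deterministic cluster-id tie-break (and a warning) on exact ties.

`target_overlap_significance` is the standard upper-tail hypergeometric test
for target-set overlap; the suite checks it against exhaustive enumeration
of all draws for small universes.

## Interval statistics

Sites are first collapsed to a fixed odd width (default 5 nt) centered on
the maximum cross-link position, ties leftmost, midpoint-centered when no
counts are available, clipped (and flagged) at region bounds. Jaccard and
per-gene overlap first union-merge the intervals within each RBP so nested
peaks are not double-counted; all quantities are nucleotide counts from
`IRanges` set operations, verified against per-nucleotide logical vectors in
the tests. The gene-level classification "overlapping" is strict
(overlap > 50 nt). Because the field leaves the denominator of a
"coincidental coverage" fraction ambiguous, `per_gene_overlap` emits it three
ways (over the union and over each RBP's coverage).

The relative-distance index summarizes positional correlation: for each
B-site midpoint inside the span of A midpoints, the distance to the nearest
A midpoint is divided by the spacing of the flanking A midpoints, folded
into [0, 0.5]; the index is 1 − 4·mean(d). The literature defines a family
of such statistics and fixes only the anchor semantics (+1 coincident, 0
uniform, −1 perfectly even interleaving); this estimator is the simplest one
satisfying all three anchors, and the tests pin each anchor plus the
near-zero behaviour of uniform placement. B midpoints outside A's span are
excluded (they have no flanking pair), and genes with fewer than two A sites
are skipped with a message.

## Conservation against shuffled-site nulls

`observed_vs_shuffled` compares each gene/feature's mean binding-site
conservation with 10 re-placements of the same sites uniformly at random
within the same feature (widths preserved, non-overlapping). Ten iterations
is the conventional choice here; it bounds the per-gene empirical p at
1/11 ≈ 0.09, which is why inference is done *across* genes: a one-sided
Mann–Whitney U of observed means versus the pooled shuffled means, with
Bonferroni adjustment across feature kinds. Both the per-gene empirical p
and the pooled group test are reported, since the field's practice is
ambiguous between them. The module is score-agnostic (phastCons-like
bounded or phyloP-like unbounded tracks) because every comparison is
rank-based. Pooling shuffled means across genes mildly violates
independence (shuffles of one gene share its track), which in practice makes
the test slightly conservative; the acceptance suite measures the empirical
type-I rate over 200 null simulations and finds it at or below nominal.

## Coevolution: mutual information with average product correction

Alignments are reference-anchored: reference-gap columns are dropped at
read time with a recorded strictly-increasing column map, so site intervals
in transcript coordinates index alignment columns directly. `filter_msa`
applies the standard pre-filters — rows with non-gap fraction < 0.4 are
dropped, and of any row pair with identity > 0.98 (over mutually non-gap
columns) the later row is dropped, the reference never. Blocks left with
fewer than 4 rows are flagged low-power.

MI is computed per column pair over {A, C, G, T} with pairwise gap deletion
(rows gapped in either column are excluded for that pair). Treating the gap
as a fifth symbol was rejected because shared gap stretches generate strong
artifactual MI. Pairs with fewer than 4 effective rows are missing, as is
the diagonal. Log base 2 (bits) is used; all downstream comparisons are
base-invariant. The implementation builds the joint counts for *all* pairs
simultaneously from 16 indicator-matrix cross-products, and is checked to
1e-12 against a direct frequency-counting oracle on small alignments. APC
subtracts `mean_i × mean_j / overall_mean` from each pair, the standard
correction for shared phylogenetic signal and column entropy.

The site-pair statistic works per gene, per UTR region (5′UTR and 3′UTR are
processed independently) and per direction. For direction A→B, each A-site
column's mean corrected MI to the B-site columns (sᵢ) is paired with its row
average (rᵢ); a one-sided Wilcoxon signed-rank tests whether partner-site MI
exceeds the column's baseline. The comparison is unnamed in the field's
descriptions; a paired rank test is the natural choice because sᵢ and rᵢ
share the column's phylogenetic idiosyncrasies. P-values are
Bonferroni-adjusted across genes × regions × directions
(`site_pair_table`), significance at adjusted p < 0.01. Note the arithmetic
this implies: with n site columns the smallest one-sided signed-rank p is
2⁻ⁿ, so a gene needs roughly n ≥ log₂(tests/0.01) site columns to be
callable at all; the package's standard simulated geometry uses three
width-5 sites per RBP (15 columns), comfortably above that floor. The
shuffled null (`shuffle_null`) re-places the *partner's* sites uniformly in
the region, 10 iterations per gene per direction, and `shuffle_summary`
compares observed versus shuffled pair means paired across genes.

## Steady-state half-life from smFISH

Three equations chain the estimate: transcription rate =
(nascent / w) × elongation / gene length, with elongation 90 kb/h; decay =
(chromosome fraction × rate × copies) / mature per cell; t½ = ln 2 / decay
× 60 (minutes). The probe-library weighting factor w converts partial
nascent signal into polymerase equivalents: a nascent transcript lights only
probes fully 5′ of the polymerase, so with a uniformly positioned
polymerase, w = mean over probes of (L − s − ℓ)/L. This integral definition
is validated by its limits (probes at the 5′ end → w → 1; uniformly dense
probes → w → 0.5) and against discrete enumeration over all polymerase
positions. Nascent signal is averaged over transcription-site-positive
cells, mature counts over all cells. The chromosome fraction is either
estimated as the TS-positive cell fraction (`cf_mode = "ts_fraction"`) or
fixed (`cf_mode = "fixed"`, e.g. 2 when both loci are scored as one unit);
chromosome fraction and copy number are deliberately independent knobs
because the field's usage conflates them (a fixed fraction of 2 may already
subsume diploidy) — the package exposes both and resolves nothing silently.
The CI is a percentile bootstrap over cells (default 1000 resamples, 80%
coverage level).

## What the generators emulate — and what they don't

Every generator is a pure function of its `sim_spec` (seed included) and
returns its ground truth alongside the data.

* **Cross-link tracks**: 600 genes, six temporal archetype profiles over
  four libraries (RBP1-L1, RBP1-L2, RBP2-L2, RBP2-L3) × 3 replicates;
  per-gene totals are negative-binomial (θ = 10) around archetype ×
  TPM (log-normal, median 50), spread over a few fixed peak positions, on
  top of Poisson background flagged nonsignificant. Library sizes are
  library-wide usable-read totals (nominal 10⁶ with 5% log-normal replicate
  jitter) of which the simulated genes are a subset. Real iCLIP adds
  position-level autocorrelation, mappability holes and antibody batch
  effects, none of which are modelled; recovery results say the pipeline
  works when its distributional assumptions hold, not that real libraries
  satisfy them.
* **Alignments**: a star phylogeny — species drawn i.i.d. from the
  reference with 30% per-site substitution — rather than a tree. This is
  sufficient because the MI statistic itself is tree-agnostic; shared
  branches in real phylogenies inflate background MI, which is exactly what
  APC absorbs. Planted pairs copy the substitution *event* with the stated
  coupling probability through a fixed bijective recoding, so coupling 1.0
  gives MI equal to the column entropy and coupling 0.0 is exact
  independence. Gaps are injected i.i.d. per cell at 5% by default;
  real alignments gap in blocks.
* **Conservation**: i.i.d. Beta scores, background mean 0.1 (Beta(1,9)),
  under-site mean 0.8 (Beta(8,2)). Real conservation tracks are strongly
  autocorrelated; the shuffle test's calibration under autocorrelation is
  not established by these simulations.
* **smFISH**: Poisson mature counts around the closed-form steady state and
  Poisson nascent counts around rate × residence × w, with TS-positive
  cells Bernoulli(chromosome fraction). Cell-to-cell extrinsic noise
  (bursting, size effects) is absent, so real CIs will be wider than
  simulated ones.

## Problem sizes and runtime choices

The test and acceptance workloads use 600 genes × 5 seeds for clustering,
50 genes of 27 species × 200 columns for coevolution power (plus 50 null
genes), 100 planted plus 200 × 20 null gene sets for conservation
calibration, and 20 seeds × 50 cells × three half-lives for recovery —
sizes chosen so the full suite completes in well under a minute per module
on one core while keeping every statistical assertion comfortably powered.

## Known limitations

* The temporal profile filter is a stand-in, not a re-implementation of any
  specific time-course DE package; with more stages its design matrix would
  need revisiting.
* The relative-distance index is one member of a family; other folds of the
  same quantity differ away from the anchor points.
* The coevolution module assumes the alignment is correct; misalignment
  masquerades as covariation and no correction is attempted.
* Half-life estimation presumes steady state; genes being actively induced
  or repressed violate the production/decay balance and will bias t½ in the
  direction of the transient.
* BAM/FASTQ handling, peak calling, motif discovery, ortholog mapping and
  image quantification are out of scope: the package starts from called
  sites, tracks and counted spots.
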