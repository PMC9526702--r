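---
title: "Methods: random-forest niche deconvolution of bulk proteomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: random-forest niche deconvolution of bulk proteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichedeconv)
```

# The model

Glioblastoma bulk proteomes are treated as mixtures of five histomorphologic
niches: leading edge (LE), infiltrating tumor (IT), cellular tumor (CT),
microvascular proliferation (MVP), and pseudopalisading cells around
necrosis (PAN), always in that canonical order. The package estimates the
niche composition of a bulk sample indirectly, through a classifier: a
random forest trained to tell pure microdissected niche regions apart is
applied to a mixed bulk profile, and the fraction of trees voting for each
niche is read out as that niche's relative abundance. The vote fractions are
non-negative and sum to one by construction (each tree casts exactly one
vote), so every composition estimate lies on the 4-simplex with no
renormalization. The niche with the largest vote share is the sample's
"dominant" or "...-like" signature; exact ties are broken by the canonical
order.

This is a pragmatic rather than a generative estimator. Tree-vote fractions
are not calibrated tissue-area fractions; they are monotone indicators of a
niche's contribution. Accordingly the package validates them as such: on
synthetic mixtures, the dominant niche should be recovered when the true
dominant weight is large, and the vote share of the true dominant niche
should correlate (rank-wise) with its true weight. Alternative deconvolution
backends (non-negative least squares, support-vector regression) are out of
scope by design.

## Classifier

Each of `n_trees` (default 200) classification trees is grown on a bootstrap
resample of the training regions, with `floor(sqrt(p))` randomly drawn
candidate features per node and Gini impurity as the split criterion. Depth
is unlimited; a node stops splitting when its majority class reaches
`purity_stop` (default 0.95) of the node, when it is pure, or when it has
fewer than two samples. The purity rule is the per-tree reading of "grow
until 95% of classes are accurately classified": it is the only mechanism
that acts during tree growth, and it is exposed as a tunable parameter
(`purity_stop = 1` grows to full purity).

Two numerical choices make the forest reproducible in a strong sense:

* Per-tree seeds are derived from the master seed, and each node draws its
  candidate features from a seed that is a deterministic function of the
  tree seed and the node's bootstrap sample multiset. A tree stopped at 95%
  purity is therefore exactly a pruned version of the tree grown to full
  purity (never deeper), and predictions are invariant to the row order of
  the input matrix (features are internally sorted by protein id).
* Class votes are hard votes (one per tree); the dominant label uses
  first-maximum tie-breaking in canonical niche order.

Performance on held-out reference regions is summarized by the confusion
matrix and the macro-averaged one-vs-rest AUC computed from vote fractions
via the rank-sum identity (average ranks for ties). Macro averaging was
chosen because a single multiclass AUC must aggregate five binary curves
somehow and the unweighted mean treats rare and common niches equally; the
per-class AUCs are always reported alongside.

## Train/test protocol

The stratified split assigns `ceiling(train_frac * n)` units per niche to
training (default 80%). The split unit is the patient-niche *region*, so
technical duplicates of one region never straddle the split — otherwise a
duplicate of a training sample in the test set would inflate hold-out
performance. Splitting by individual columns is available
(`split_by = "sample"`) for comparison.

Both the reference matrix and bulk matrices are z-scored per sample before
training and prediction (toggle `zscore_training`). Harmonizing both sides
with the same transform is the conservative reading of a cross-platform
workflow in which label-free reference intensities and isobaric-tag bulk
intensities live on different scales: z-scoring is invariant to per-sample
affine changes with positive slope, which is exactly the family of
distortions the synthetic platform shift emulates.

# Preprocessing

The pipeline enforces its own order through a `scale_tag` that only moves
forward: `raw -> log2 -> log2-imputed -> zscored`.

* **Presence filter.** A protein is kept when observed in at least
  `min_frac` (default 0.6, inclusive: 3 of 5 passes) of the samples of at
  least one group. The operation is idempotent and preserves row order.
* **Downshifted-Gaussian imputation.** Missing values in sample `j` are
  drawn from `N(m_j - downshift * s_j, (width * s_j)^2)`, with `m_j`, `s_j`
  the observed mean and SD of that sample (global moments optional, and the
  automatic fallback when a sample has fewer than two observed values). The
  shipped default is `downshift = 0.3, width = 1.8`; the conventional
  Perseus preset (`downshift = 1.8, width = 0.3`) is available as
  `imputation_params_perseus()`. The two parameterizations are transposes of
  one another and the literature uses both orderings; neither is asserted as
  canonical, and the test suite checks the moment contract under both.
* **Z-scoring.** `(x - mean)/sd` per sample with the `n - 1` SD; a
  zero-variance column is an error naming the sample.
* **Feature intersection.** Exact, case-sensitive gene-symbol matching;
  Perseus-style multi-id strings (`"A;B;C"`) are reduced to the leading
  symbol only when both matrices carry them. Output rows are sorted so the
  two matrices align deterministically.

# Cohort statistics

## Moderated volcano with permutation FDR

Per protein, `t_s0 = (mean_A - mean_B) / (s_pooled * sqrt(1/n_A + 1/n_B) + s0)`
with the pooled-variance denominator (Welch optional) and `s0 = 0.1` by
default; `s0 = 0` reduces exactly to the textbook pooled t. Significance
uses a symmetric cutoff on `|t_s0|`: group labels are permuted `n_perm`
times (default 250), and the estimated FDR at a cutoff is the summarized
permutation exceedance count divided by the observed exceedance count. The
smallest cutoff with estimated FDR at or below the target defines the
significant set.

The exceedance summary is the **mean** over permutations by default. The
median — the classical SAM summary — degenerates at the most extreme
cutoffs: at the observed maximum the observed count is 1 while the median
permuted count is 0 in roughly half of null datasets, which spuriously
calls the single most extreme protein with estimated FDR zero. The mean
summary keeps the numerator positive (about 0.5 at the observed maximum
under the null) and empty null volcanoes stay empty; `perm_summary =
"median"` restores the SAM behavior for comparison. Proteins with zero
difference and zero spread (a statistic of 0/0) are never called.

## Marker contrasts

One-tailed Welch t-tests in a caller-stated direction — the direction is a
required argument and never inferred from the data — with Benjamini-Hochberg
q-values over all tested proteins. The degenerate case (zero variance in
both groups) gets `p = 0.5` at zero difference and 0/1 by sign otherwise,
with a message.

## Subtype-by-niche enrichment

Pearson chi-squared on the observed subtype-by-dominant-niche table, with
expected counts from the product of margins; empty rows/columns are dropped
before computing `df = (r-1)(c-1)`. A `focus = c(subtype, niche)` pair adds
the 2x2 collapse (focus subtype vs rest, focus niche vs rest) with its own
statistic — this is the targeted test for "is the IT-like signature enriched
in proneural tumors". No continuity correction by default (Yates optional
for the 2x2); expected cells below 1 trigger a warning recommending collapse
or an exact test rather than silently switching methods.

## Ordination and clustering

PCA treats samples as observations with per-protein mean centering and no
scaling; component signs follow a deterministic convention (the
largest-magnitude loading is positive). Hierarchical clustering uses
`1 - Pearson r` between samples and average linkage. Group-level
cross-matrix agreement uses Spearman correlation of group-averaged protein
vectors with average-rank tie handling. All three delegate to the standard
R implementations (`prcomp`, `hclust`, `cor`), wrapped for the package's
containers and error conventions.

# The synthetic-data generator

The generator is first-class, tested code: it defines the study conditions
under which every downstream property is demonstrated.

**Reference atlas.** Protein `i` in duplicate `d` of niche `k` in patient
`q` is `baseline_i + effect * 1[i is a marker of k] + u_q + e`, all in log2
units, with `baseline_i ~ N(25, 2)` (a label-free-intensity-like scale),
patient intercepts `u_q ~ N(0, patient_sd)` and residual `e ~ N(0,
noise_sd)`. Defaults: 4,794 proteins (the atlas scale), 20 patients, 2
technical duplicates per region (200 reference columns), 100 disjoint
marker proteins per niche elevated by 2 log2 units, and `patient_sd =
noise_sd = 0.5`. The marker count and effect are a judgment call — a few
percent of the proteome per niche, with an effect about four residual SDs —
representing clearly niche-enriched programs without making the problem
trivial at the mixture level; the atlas counts themselves are config
because the published descriptions of comparable atlases are not fully
internally consistent (regions vs samples vs duplicates), so none of the
candidate counts is hard-coded.

**Missingness.** A value is censored when its noisy proxy `x + eps`,
`eps ~ N(0, 0.5)`, falls below the matrix-wide `missing_censor_quantile`
(default 0.1). This is intensity-dependent (missing-not-at-random)
left-censoring — the regime the downshifted-Gaussian imputation assumes —
and it is monotone in the quantile for a fixed seed.

**Bulk cohort.** Each bulk sample's expected profile is the weighted
arithmetic mean of the five niche mean profiles on the **log** scale.
Mixing in log space (rather than mixing linear intensities) matches what
the classifier consumes — log-scaled, z-scored data — and keeps the
generative weights interpretable on the scale where all inference happens.
Weights are Dirichlet with base concentration 1 per niche; a subtype's
coupling entry multiplies one niche's concentration (default: proneural
couples to IT with factor 6, giving IT a clear but not deterministic
majority among proneural samples). Normal-brain controls get weight 1 on
LE. A global affine platform shift (`0.8 * x + 5` by default) moves the
bulk matrix off the reference scale so that the z-score harmonization step
is load-bearing rather than decorative. Subtype frequencies default to
25/25/30/10/10 percent for proneural/classical/mesenchymal/IDH-mutant/
normal over 110 samples, a discovery-cohort-like composition.

**What the generator does not emulate:** peptide/spectrum-level artifacts,
protein-inference ambiguity, isobaric reporter compression, batch effects
beyond the single affine shift, correlated protein modules, or heavy-tailed
noise. Passing tests therefore demonstrate the pipeline's internal
correctness and its behavior under a plausible MNAR-censored mixture model,
not performance on any real cohort.

# Problem sizes and seeds

Unit tests run at reduced scale (typically 600 proteins, 8 patients, 60
bulk samples) so the suite stays fast; the end-to-end validation and the
acceptance script use the full default scale (4,794 proteins, 200 reference
columns, 110 bulk samples, 200 trees), 100 replicates for the enrichment
power/calibration rates, 20 seeds for the null volcano, and 100
permutations per volcano. Every stochastic step takes an explicit seed; the
pipeline driver derives per-stage seeds from a single master seed via a
small deterministic byte hash, so one integer reproduces a whole run
bit-for-bit (manifest checksums included).

# Known limitations

* Vote fractions compress toward the interior of the simplex: a sample that
  is 100% CT rarely gets a CT vote share of 1, because individual trees
  still disagree near split boundaries. Rank-based validation (Spearman) is
  the honest summary; absolute weights should not be read off the vote
  shares.
* The permutation FDR has limited resolution at small `n_perm`, and the
  complete-enumeration warning fires when `n_perm` exceeds the number of
  distinct label shuffles.
* With few samples per subtype, the focused 2x2 chi-squared can have small
  expected cells; the package warns and leaves the choice of an exact test
  to the analyst.
* The classifier assumes the bulk matrix shares the reference feature space
  after `intersect_features`; proteins absent from the bulk platform are
  simply dropped, which can remove niche markers and degrade composition
  estimates on real data.
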