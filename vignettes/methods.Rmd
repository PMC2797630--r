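---
title: "Methods: latent semantic factors in word-evoked activation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: latent semantic factors in word-evoked activation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models it implements, the
choices that were genuinely open, and what its synthetic-data validation
does and does not establish.

## The data model

The unit of analysis is a per-presentation activation value for each
(participant, presentation, word, voxel) cell: a 60-word stimulus set (five
exemplars from each of twelve taxonomic categories), presented six times,
measured at gray-matter voxels of 3.125 × 3.125 × 6 mm that are partitioned
into five bilateral "lobes" (frontal, parietal, temporal, occipital, and a
fusiform/parahippocampal lobe). The package does not model hemodynamic time
series: the generator emits the already-averaged per-presentation images
that all downstream analyses consume, and real preprocessing (slice timing,
motion correction, spatial normalization) is out of scope.

A voxel's **activation profile** is its vector of 60 responses within one
presentation (or averaged over several). Its **stability** is the mean
Pearson correlation between profiles over all unordered presentation pairs
— a reliability screen that selects voxels whose word response is
reproducible. In cross-participant analyses, each training participant's
six-presentation mean profile is treated as one pseudo-presentation and
stability is the mean pairwise correlation across participants.

## Two-level factor analysis

At the first level, for each participant and lobe, the 50 most stable
voxels' mean profiles (normalized to mean 0 / SD 1 over words) are
intercorrelated and factored. Writing $v_i$ for voxel $i$'s profile, the
model is $v_i = \sum_j c_{ij} F_j$ with loadings $c_{ij}$ and factor
profiles $F_j$ (factors over words). Factor extraction is iterated
**principal axis factoring**: the correlation matrix's diagonal is replaced
by communality estimates, the top-$k$ eigenpairs give loadings, and
communalities are re-estimated until the largest change falls below
tolerance. The loadings are rotated to simple structure by **varimax**
(Kaiser row normalization); rotation preserves each item's communality and
leaves the least-squares fit unchanged because the rotation is absorbed
into the profiles. Factor profiles are then solved by ordinary least
squares from $V = CF$, and their rows are the per-word factor scores.

At the second level, the pooled first-level factor profiles (5 factors × 5
lobes × the analyzed participants; 100 items for four participants) are
themselves standardized, intercorrelated, and factored the same way with 10
factors, recovering dimensions common across lobes and participants.

A voxel is uniquely assigned to the first-level factor carrying its highest
absolute loading if that loading exceeds 0.4; the same rule maps
first-level factors to second-level factors; composition yields a voxel →
second-level-factor map. A factor's **commonality** is the number of
distinct participants contributing assigned voxels. Each factor's share of
explained variation is its sum of squared loadings divided by the item
count.

### Numerical choices

* **SD convention.** Sample SD (denominator $n-1$) everywhere, so the
  worked examples in the tests are exact.
* **PAF initialization and convergence.** Initial communalities are squared
  multiple correlations when the correlation matrix is invertible. The
  second-level matrix (100 items from 60 words) is singular by
  construction, so the fallback is each row's maximum absolute off-diagonal
  correlation — standard practice for deficient matrices. Convergence is
  max absolute communality change < 1e-4; the extraction function defaults
  to 100 iterations, while the pipeline entry points allow up to 1000
  because rank-deficient matrices approach their fixed point slowly.
  Negative eigenvalues of the reduced matrix are clamped to zero.
* **Null factors.** On (nearly) noiseless data a lobe's correlation matrix
  has lower rank than the requested number of factors; surplus factors come
  out with null loadings. They are dropped (sum of squared loadings below
  1e-6) before the least-squares solve, which would otherwise be
  unidentifiable. Under realistic noise all requested factors survive, so
  the canonical configuration yields exactly 100 second-level inputs.
* **Sign and order.** After rotation each factor is flipped so its
  largest-magnitude loading is positive and factors are ordered by
  decreasing sum of squared loadings, making outputs deterministic. Factor
  profiles are still only identified up to sign and permutation, so all
  recovery checks align factors to references by exhaustively maximizing
  total absolute correlation.
* **Ties** in stability ranking break by ascending voxel id.

## Localization

Each second-level factor's assigned voxels are grouped into connected
components (26-neighborhood by default, configurable to 6 or 18; the
appropriate neighborhood is not settled in this literature, and 26 is the
permissive reading). Components with fewer than five voxels are discarded.
A retained cluster is summarized as a sphere at the centroid of its member
voxel centers (in mm) with radius equal to the members' mean radial
dispersion. Feature-selection **search volumes** are cuboids: the bounding
box of the sphere, expanded by one voxel per direction and clipped at the
grid. Because the mean radial dispersion can be smaller than the farthest
member's distance (e.g. an elongated cluster), the implementation grows the
box to cover all member voxels before expanding, so a search volume always
contains its cluster.

## Decoding

The classifier is Gaussian Naive Bayes with pooled variance: per-class
feature means, and a single per-feature variance estimated as the sample
variance of all training values after subtracting each value's class mean
(denominator $N-1$). Priors are the training class frequencies (uniform in
this balanced design). Classification ranks all 60 labels by log posterior;
performance is the normalized rank accuracy $(N - r)/(N - 1)$, whose chance
level is 0.5.

Within-participant evaluation enumerates all $\binom{6}{2} = 15$ folds:
stability and feature selection use only the four training presentations;
activations are z-scored per feature across words separately for training
and test; the mean of the two held-out presentations is classified.
Cross-participant evaluation leaves one participant out entirely — their
data are never touched by selection or training — and treats the ten
training participants' mean images as ten pseudo-presentations.

Feature policies: *factor-based* selects, in each search volume, the five
voxels maximizing |correlation with the factor profile| × stability (the
absolute value is taken because rotated factors have arbitrary sign; a
signed variant is available); with 16 volumes this yields 80 voxels.
*Stability-only* selects the 80 most stable voxels anywhere in cortex.
Single-factor and semantic-only variants restrict to the chosen factors'
volumes. Significance thresholds come from permutation runs: one random
relabeling of the training words is drawn per run and applied in every
fold, and the threshold is the empirical $(1-\alpha)$ quantile of permuted
mean accuracies. (How the original analyses permuted labels is unstated;
this scheme is deterministic given a seed and preserves the train/test
separation.)

## Zero-shot generative prediction

For each of the $\binom{60}{2} = 1770$ held-out word pairs (a seeded
subsample is supported because the per-fold factor re-runs dominate
runtime): the two-level factor analysis is re-run on the 58 training words
using reference participants (excluding the analyzed participant), its top
four factors are localized, and 80 voxels are selected per fold. A
per-voxel ordinary least squares regression on the factor-score predictors
(plus intercept) is fit over the 58 words; the two held-out words are
predicted from behavioral 1–7 ratings of the three semantic dimensions plus
word length, standardized using the training words' statistics so that
factor-score and rating predictors share a scale. Predictions are matched
to the two observed images by total cosine similarity (straight vs swapped
pairing); exact ties count as incorrect, a conservative rule. The binomial
chance threshold for $n$ trials at level $\alpha$ is the smallest
proportion $k/n$ with $P(X \ge k) \le \alpha$ under fair coin matching —
0.537 for 1,770 trials at $\alpha = .001$.

Open choices resolved here:

* **Predictor alignment.** Recovered factors are matched to rating
  dimensions by exhaustive permutation maximizing total absolute
  correlation over the training words, with sign flips. (Human analysts
  match factors to scales by interpreting top-scoring words; an automated
  pipeline needs an explicit rule.)
* **Predictor source.** The default trains on per-fold factor scores and
  tests on z-scored ratings; a `ratings`-for-both mode is provided, and in
  that mode activation that is exactly linear in ratings and word length is
  predicted exactly.
* **Observed-image normalization.** The held-out words' images are
  normalized per voxel with the mean/SD computed on the 58 training words
  only, so no statistic of the test words leaks into the model.
* **Degenerate inputs.** On signal-free data no voxel cluster survives the
  0.4-loading/5-neighbor rule, so the factor-based protocol has no feature
  set; the `stability_only` feature mode (the baseline that uses the 80
  most stable voxels) covers that regime and is what the chance-level
  checks use.

The cross-participant generative variant trains the regression on the
other participants' pooled mean images for the 58 words and matches the
held-out participant's two images.

## The synthetic generator

The generator is first-class, tested code; its defaults are the study
conditions the package targets. Eleven participants × six presentations ×
the fixed 60-word set (analyses that emulate the four-participant discovery
phase pass `n_participants = 4` explicitly); a 15 × 12 × 10 voxel grid of
3.125 × 3.125 × 6 mm voxels in five x-slabs ("lobes"); four planted factors
— three semantic profiles built as category-indicator mixtures (e.g.
*eating* loads on vegetables and kitchen utensils) with small seeded
within-category jitter, z-scored, plus the z-scored letter count as a
word-length factor; clusters per factor of 5, 4, 3 and 4 (16 total,
mirroring the canonical per-factor location counts), each a 19-voxel sphere
of radius 1.5 voxel indices confined to one lobe, placed on a staggered
lattice so clusters can never merge; loadings drawn uniformly in
[0.8, 1.2] inside clusters and exactly zero outside. Activation is
`gain_p × Σ_k loading × profile + noise` with `gain_p ~ N(1, 0.1²)` and
independent Gaussian noise of SD 0.3 on the signal scale (the noise
distribution and its spatial structure are not documented for this
paradigm; independence is an assumption, not an inference). Ratings are
affine rescalings of the true semantic profiles into [1, 7] with truncated
noise (SD 0.5 rating units by default). With `shared_code = FALSE` each
participant receives idiosyncratic cluster placements, loadings *and*
factor profiles — the control condition under which cross-participant
decoding must collapse while within-participant decoding is unaffected.

Word-indexed randomness is drawn in alphabetical word order, so permuting
the word set permutes every output identically.

**What passing tests show — and don't.** The generator emulates the
*statistical* structure the analysis assumes: a low-rank common code, lobe-
confined compact clusters, independent noise, scalar participant gains. It
does not emulate spatially correlated noise, imperfect inter-participant
registration, hemodynamic confounds, or semantic structure beyond the
planted factors. Recovery on this data validates the implementation — that
the pipeline finds what is there — not the scientific claim that real
cortex is organized this way.

## Problem sizes and limits

The validation suite uses 4-participant datasets on the 1,800-voxel default
grid; the zero-shot checks use seeded 20–100-pair subsamples of the 1,770
folds (the full enumeration is available via `pairs = "all"`); permutation
bands use 20 runs at the corresponding α rather than the 1,000+ runs a
p < .001 threshold would need. Limit checks labeled "noise-free" use a
noise SD of 0.02 (2% of signal): exactly zero noise makes zero-loading
voxels constant (stability is then undefined, and the package treats that
as an error rather than guessing) and produces tied degenerate spectra
that stall communality iteration.

Known limitations: oblique rotations and confirmatory factor analysis are
not provided; factor-number selection beyond eigenvalue inspection is the
user's responsibility; the headline accuracies reported for real cortex in
this literature (e.g. rank accuracy ≈ 0.72, generative accuracy ≈ 0.80)
are not reproducible here because the underlying scanner data were never
deposited — the package's claims are about correctness on data with known
ground truth.
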