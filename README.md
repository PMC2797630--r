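# neurosem

Two-level factor analysis and decoding of word-evoked brain activation.

## The problem

When a person reads a concrete noun like *apple* and thinks about the
object, the evoked fMRI activation pattern carries information about the
word's meaning. This package implements an analysis pipeline for asking, in
a data-driven way, *which semantic dimensions* organize those patterns and
*where* they live in cortex — and for testing the answer with machine
learning:

1. **Stability screening.** A voxel's *stability* is the mean pairwise
   Pearson correlation of its 60-word activation profiles across repeated
   presentations of the word set; only reliable voxels enter the analysis.
2. **Two-level exploratory factor analysis.** For each participant and each
   of five brain "lobes" (frontal, parietal, temporal, occipital,
   fusiform), the intercorrelations of the 50 most stable voxels' profiles
   are factored by principal axis factoring with varimax rotation
   (first level, 5 factors each). The pooled first-level factor profiles
   are factored again (second level, 10 factors) to find dimensions common
   across lobes and participants. Writing `v_i` for voxel i's 60-word
   profile, `F_j` for first-level factor profiles and `c_ij` for loadings,
   the first-level model is `v_i = Σ_j c_ij F_j`; the second level models
   the `F` profiles as combinations of higher-order profiles `G_k`. Factor
   profiles are recovered by least squares and constitute per-word factor
   scores.
3. **Localization.** Voxels are uniquely assigned to the factor carrying
   their highest absolute loading (threshold 0.4, applied at both levels);
   connected clusters of at least five assigned voxels are summarized as
   spheres (centroid + mean radial dispersion), yielding a table of factor
   locations and cuboid search volumes for feature selection.
4. **Decoding.** A Gaussian Naive Bayes classifier with pooled variance
   identifies which of the 60 words a person is thinking about, scored by
   normalized rank accuracy `(N − rank)/(N − 1)` (chance 0.5). Features are
   80 voxels — five per search volume by the product of factor-correlation
   and stability, or the 80 most stable voxels as a baseline — selected
   from training data only, in a leave-two-presentations-out (15-fold)
   within-participant design or a leave-one-participant-out cross design.
5. **Zero-shot generative prediction.** For each of the 1,770 word pairs, a
   per-voxel regression on factor-score predictors is trained on the
   remaining 58 words (with the factor analysis re-run per fold), the two
   held-out words' images are predicted from independent 1–7 semantic
   ratings plus word length, and predictions are matched to observations by
   cosine similarity (chance 0.5; the p < .001 binomial threshold for 1,770
   trials is 0.537).

Real scanner data for this paradigm are not publicly deposited, so the
package ships a **synthetic data generator** (`generate_dataset()`) that
plants a known ground truth — semantic factor profiles built from the
12-category structure of the 60-word set, plus a word-length factor; voxel
clusters confined to single lobes; participant gains and Gaussian noise —
so every stage of the pipeline can be validated against what was planted.
The intended users are researchers who want a tested, inspectable
implementation of this family of multivariate fMRI analyses.

## Worked example

```r
library(neurosem)

cfg <- synthetic_config(n_participants = 4, noise_sd = 0.3, seed = 11)
sim <- generate_dataset(cfg)

model <- run_two_level(sim$dataset, participants = 1:4)
length(model$first_level)            # 20   (4 participants x 5 lobes)
nrow(model$second_level$loadings)    # 100  (20 analyses x 5 factors)

top <- order(-model$explained)[1:4]
align_factors(model$second_level$profiles[top, ], sim$truth$profiles)$cors
#> [1] 0.972 0.966 0.979 0.988     # planted factors recovered, |r| > 0.95
model$commonality[top]
#> F1 F2 F3 F4
#>  4  4  4  4                     # every factor common to all 4 participants

loc <- localize_factors(model, sim$dataset, factors = top)
nrow(loc$report)                     # 16 clusters (5 + 4 + 3 + 4)

res <- within_participant_cv(sim$dataset, 1,
                             list(mode = "stability_only", n_features = 80))
res$mean_accuracy
#> [1] 0.9988                      # 15-fold rank accuracy, chance = 0.5

chance_match_threshold(1770, 0.001)
#> [1] 0.5372881                   # zero-shot significance threshold (0.537)
```

The commented outputs are what the code printed for this configuration: the
two-level analysis recovers all four planted factor profiles nearly
perfectly, localizes the 16 planted clusters, and the decoder identifies
words almost without error at a signal-to-noise ratio of about 3.

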