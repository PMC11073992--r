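---
title: "Models and methods: pairwise idiosyncrasy, group consensus, and their dissociation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: pairwise idiosyncrasy, group consensus, and their dissociation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(akrsa)
```

## The scientific question

Do people who score high on a trait -- canonically, loneliness -- hold
*idiosyncratic* multivariate representations of shared cultural targets
(well-known public figures), relative both to other individuals and to the
group consensus? `akrsa` implements the two complementary analyses that
answer this, together with everything needed to exercise them end to end
on synthetic data:

1. **The pairwise "Anna Karenina" model.** Every pair of participants
   contributes one representational similarity per target (Pearson
   correlation of vectorized activity patterns, cosine similarity of text
   embeddings, or Jaccard similarity of binary trait responses). Pair-level
   similarity is regressed on the *pair mean* of the trait in a linear
   mixed-effects model. If high scorers are each idiosyncratic in their own
   way -- unhappy families, each unhappy differently -- pairs with a higher
   mean score are less similar, whoever they are paired with.
2. **The similarity-to-consensus model.** A group-consensus representation
   of each target is estimated, and each participant's similarity to it is
   regressed on their trait score.

## The dyadic mixed model

For the pairwise analysis the dyad table is *doubled*: each unordered pair
enters twice with the member roles swapped, which makes the crossed random
intercepts for "first member" and "second member" symmetric -- every
participant appears in both roles, with n − 1 rows per role. Fixed effects
and all predictors are z-scored against the analysis sample, so
coefficients are standardized betas. Random intercepts are fitted for both
pair members and the target; a boundary (zero) target variance triggers an
automatic refit without the target intercept, which is recorded in the
fit's notes.

**Undoing the doubling redundancy.** Doubling duplicates every observation,
so the fitted model believes it has twice the information it really has:
the model-based sampling variance of every fixed effect is deflated by a
factor of two, through both the duplicated residual rows and the role-split
participant intercepts (the model treats a participant's two role
intercepts as independent when they belong to the same person). The package
therefore applies the full correction to doubled fits: the Satterthwaite
degrees of freedom are halved **and** the standard error is inflated by
√2 (equivalently, t is scaled by 1/√2), with p recomputed from the
corrected t at the halved df. In simulation this brings the two-tailed
rejection rate of a true null from roughly 0.23 to 0.05 at nominal
α = 0.05; with df-halving alone the test is far anticonservative, in both
the residual-noise and participant-variance regimes. Point estimates and
the df structure (≈ n − 1 for the pair-mean effect after halving) are
unchanged by the correction.

Directional hypotheses (idiosyncrasy = *negative* coefficients) are tested
one-tailed: `p_one = p_two / 2` when the estimate's sign matches the stated
direction, `1 − p_two / 2` otherwise. Confidence intervals are Wald
intervals at the adjusted df; simulation-based intervals were considered
and rejected as a default because deterministic tests need deterministic
intervals.

**A caveat on moderation tests.** The trait-by-consensus interaction in
`consensus_moderation()` varies at the participant-by-target level, and a
random-intercepts-only model (random slopes are deliberately out of scope)
cannot propagate between-target slope heterogeneity into that term's
standard error. The interaction's point estimate is unbiased -- the test
suite verifies it is centred on zero under identical per-target slopes and
recovers planted interactions with the right sign -- but its nominal p
value should be read as anticonservative when targets are few.

## The consensus procedure

For one target, the kernel-weighted consensus is built in five steps:

1. pairwise similarities → correlation (or cosine) distances, `1 − s`;
2. a 2-D *metric, stress-minimizing* multidimensional scaling embedding.
   No SMACOF implementation was available among the package's allowed
   dependencies, so the Guttman-transform majorization is implemented
   directly (C++ inner loop), run from four initializations (classical
   scaling plus three random starts) with at most 3000 iterations each,
   keeping the lowest-stress solution. Convergence stops when the relative
   stress decrease falls below 1e-6; tests verify exact recovery of
   perfectly embeddable configurations;
3. a Gaussian kernel density over the embedding,
   f(g) = Σᵢ exp(−‖g − xᵢ‖² / 2h²), evaluated on a regular 100 × 100 grid
   over the bounding box. The kernel scale h is the smaller axis range of
   the embedding. A "kernel radius" defined as a range leaves the precise
   role of the number ambiguous; it is interpreted here as the Gaussian
   bandwidth, since a truncation radius alone would leave the kernel scale
   undefined. Grid argmax ties break at the lowest row-major node index;
   collinear embeddings fall back to the nonzero axis range, and fully
   coincident embeddings short-circuit to that point;
4. proximity weights `w_i = max_j d_j − d_i` from each participant's
   Euclidean distance to the densest node, so the furthest participant gets
   weight exactly zero; all-equal distances fall back to uniform weights,
   flagged;
5. the consensus vector: the weighted mean across participants of their
   row-z-scored patterns. Z-scoring is *within participant, across
   features* -- each participant contributes shape, not amplitude. (The
   alternative, z-scoring each feature across participants, was rejected:
   the quantity being averaged is each participant's own standardized
   pattern.)

Two alternative estimators serve as robustness checks: the unweighted mean,
and distance-based weights `max_j mean-dist_j − mean-dist_i` computed in
the original distance space without any embedding.

## The synthetic-data generator

The generator is first-class, tested code: it plants exactly the structure
the analyses assume, so every downstream stage can be validated without any
external data.

* **Loneliness scores** are truncated-normal draws (rejection sampling,
  which preserves the shape near the bounds) with mean 40.73, sd 8.32 on
  the Revised UCLA scale, truncated to the scale's 20--80 range -- values
  matching a published in-person sample.
* **Patterns** follow an additive model: `x_it = μ_t + σ(l_i) ε`, with
  prototype features `μ_t ~ N(0, 1)`, noise `σ(l) = σ₀ + β z(l)` floored at
  zero (with a warning when the floor binds), and `z(l)` standardized
  against the realized sample, mirroring the analysis-side z-scoring. Under
  this model the expected pairwise correlation has the closed form
  `var(μ) / (var(μ) + σ²)`, which the tests verify across a σ grid.
* **Calibration.** With 200 features, pairwise correlations are precise, so
  small slopes plant large standardized pairwise effects. A design-time
  simulation grid fixed `idiosyncrasy_slope = 0.032` as the default
  planting a standardized pairwise effect of ≈ −0.2 under the default
  sizes (n = 40, five targets), and 0.024 for ≈ −0.15.
* **Binary trait responses** share one consensus profile, flipped
  independently per participant and masked missing at a configurable rate;
  flips are independent of loneliness by construction.
* **Split-half volumes** plant a spherical blob whose voxels share
  per-participant condition-level signal across halves; expected voxelwise
  reliability inside the blob is `σ_s² / (σ_s² + σ_n²)`.

What the generator does *not* emulate: spatial autocorrelation between
voxels, heavy-tailed or skewed similarity distributions, target-specific
variance structure, and missingness mechanisms correlated with the trait.
Passing tests therefore demonstrate the pipeline's statistical behavior
under its own assumptions, not robustness to every property of real
imaging or survey data.

## The dissociation scenarios

The pairwise and consensus models answer different questions and need not
agree. Two scenario generators plant each direction of disagreement; both
are *synthetic stand-in constructions* designed for their stated effect
patterns, not reconstructions of any particular published simulation.

* **`cluster` (consensus effect without a pairwise effect).** The top ~30%
  of scorers form a secondary cluster displaced from the main mass by a
  shared offset, with the same noise scale as everyone else. Lonely pairs
  are at least as similar as the average pair, yet every lonely participant
  sits far from the consensus. The lonely fraction is kept below half so
  the kernel-density mode stays anchored in the majority mass (with a 50/50
  split and the very wide bounding-box bandwidth, the mode can drift
  between the groups).
* **`ring` (pairwise effect without a consensus effect).** There is an
  exact obstacle to planting this direction in point estimates: to first
  order, the pair-mean coefficient is a function of each participant's
  similarity *row sum*, and so is similarity to any averaged consensus --
  the two estimands coincide. Mutually repelled deviations alone (unit
  vectors summing to zero at a matched radius) therefore produce a pairwise
  spread that the pair-mean model cannot convert into a slope. The honest
  dissociation channel is *power*: the pairwise model sees thousands of
  dyads, the consensus model only n participants. The ring construction
  accordingly places the top quartile of scorers at mean-centred (hence
  negatively correlated) deviations at a radius matched to their own noise
  magnitude, corrects each lonely deviation by the non-lonely mean noise so
  the expected overlap with the consensus is matched across groups, and
  adds a weak global idiosyncrasy gradient (slope 0.008) that the
  3000-dyad pairwise model detects reliably while the consensus regression,
  at its sample size, almost never does. Geometry checks confirm the
  construction: the standardized group difference in correlation distance
  to the consensus stays within ±0.2 while the within-lonely pairwise
  distance exceeds the within-non-lonely distance by more than half a
  pooled standard deviation.

## Reliability-based voxel selection

Voxelwise reliability is the per-participant correlation, over conditions,
between the two split-half parameter-estimate vectors at each voxel,
averaged into a group map. Candidate ROIs are grown as the connected
suprathreshold component containing a peak voxel (6-neighbour face
connectivity by default; 26 optional -- the choice is configuration, since
either is defensible). Multivoxel pattern reliability (pattern correlation
across the mask between halves, averaged over conditions then participants)
is traced across a threshold grid; each region's curve is z-scored across
thresholds, the z-curves are averaged across regions, and the argmax
threshold is selected, ties resolving toward the lower threshold (the
larger ROI). Default grid step 0.002 over a configurable range; the peak is
the map's maximum within a user-supplied anatomical search region.

## Replicate-study sizes

The packaged replicate studies use: Type-I calibration at n = 30, 3
targets, 200 features, 400 replicates; power at n = 40, 5 targets, 200
replicates; dissociation at n = 30, 5 targets, 200 replicates per scenario.
These sizes give binomial standard errors of about 0.01--0.035 on the
reported rates while keeping a full run at desk scale on a single core.

## Known limitations

* The √2 redundancy correction assumes the doubled model's variance
  deflation factor is exactly two; this is exact in the pure-residual and
  pure-participant-variance regimes and verified by simulation in mixtures,
  but it is an analytical correction, not a resampling method.
* The moderation interaction's standard error understates between-target
  heterogeneity (no random slopes), as noted above.
* Undefined similarities (zero-variance patterns, empty Jaccard overlap)
  are flagged and excluded from fits with recorded counts -- never imputed.
  A dataset dominated by such rows will fit on very little data and says
  so in the manifest.
* The MDS embedding is 2-D by design, matching the interpretability goal
  of the consensus procedure; no higher-dimensional embedding is offered.
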