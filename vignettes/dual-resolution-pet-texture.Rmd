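---
title: "Texture analysis of dual-resolution breast PET: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture analysis of dual-resolution breast PET: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question the pipeline addresses

Dedicated breast PET (dbPET) resolves sub-centimeter structure that a
whole-body PET/CT cannot: its reconstructed voxels are roughly 60 times
smaller (0.78 x 0.78 x 2.34 mm vs 4.11 x 4.11 x 5 mm) and its
post-reconstruction smoothing is far narrower (1.17 mm vs 5 mm FWHM). Does
that resolution advantage translate into better *texture-based*
classification of tumor characteristics — T-category, nodal status,
molecular subtype, Ki67 proliferation level — or do the two modalities carry
equivalent discriminative information once a lesion is large enough to be
delineated on both?

`pettex` implements the full analysis needed to pose that question
quantitatively: paired-modality phantom simulation, relative-threshold
lesion delineation, a 38-feature texture engine over four 3D gray-level
matrices, per-feature rank tests, and PCA-reduced ROC classification with a
paired curve comparison. Because no clinical volumes ship with the package,
a first-class synthetic cohort generator stands in for patients; every
statistical property the package claims is demonstrated on data it
generates itself.

## The phantom model

A lesion is an ellipsoid of elevated uptake on a uniform background,
rendered on a fine isotropic grid (0.5 mm by default) and then pushed
through each scanner model:

1. **Heterogeneity.** Intra-tumoral heterogeneity is a Gaussian random
   field: white noise convolved with an isotropic Gaussian kernel of the
   stated correlation length, standardized to unit SD inside the lesion and
   scaled by `heterogeneity_amplitude * lesion_mean_suv`. The default
   correlation length is 1.5 mm — millimetric texture, on the order of the
   dbPET voxel and well below the wbPET voxel, so the fine scanner can
   resolve structure that the coarse one averages away. The field is a
   modeling convenience, not a tumor-biology claim: any smooth seedable
   stochastic texture serves, and the amplitude is the single monotone
   "heterogeneity knob" the tests exercise.
2. **Point-spread function.** Separable Gaussian convolution at the
   modality's FWHM, applied on the fine grid. Kernel rows are renormalized
   at the volume boundary so a constant field is preserved exactly.
3. **Partial volume.** The blurred volume is rebinned to the modality grid
   by overlap-weighted averaging: each coarse voxel is the length-weighted
   mean of the fine voxels it covers, per axis. The voxel-0 centers of the
   two grids coincide (the package-wide convention puts the center of voxel
   (0,0,0) at the physical origin). Weights are renormalized per coarse
   voxel, so constants are again preserved exactly; total activity is
   conserved to well under 1% whenever the activity sits away from the grid
   boundary, which the conservation tests enforce by using a cold
   background.
4. **Noise.** Additive voxelwise Gaussian noise in SUV units, clipped at
   zero, applied after rebinning. Count-statistics realism (Poisson noise,
   reconstruction correlations) is deliberately out of scope; both
   modalities receive the same noise SD (0.05 SUV by default).

Cohorts draw one phantom per lesion from per-class parameter ranges. The
default design mimics a 44-lesion breast-cancer cohort: T-category is the
*driver* label whose classes differ in lesion size (semi-axes roughly
following AJCC size bands: Tis 3–5 mm, T1 5–9 mm, T2 9–15 mm, T3 15–18 mm,
kept inside a 56 mm field of view), while N-category, molecular subtype and
Ki67 are assigned independently of the phantoms from realistic cohort
proportions — they carry no signal by construction, which is exactly what a
null characteristic should look like downstream. Lesion mean SUV is drawn
from 6–10 on a 0.8 background, a lesion-to-background ratio of roughly
8–12, so the 40% relative threshold is comfortably exercisable; the
faint-lesion regime (ratio near 1/0.4) is covered separately by dedicated
tests. All draws descend deterministically from one master seed.

```{r}
library(pettex)
design <- cohort_design(n_lesions = 44, seed = 1)
cohort <- generate_cohort(design)
cohort$labels
```

## Lesion delineation

The delineation rule is a relative threshold: SUVmax is the hottest voxel
inside a user-supplied spherical VOI, and the mask is the 26-connected
component of voxels at or above 40% of SUVmax that contains that hottest
voxel, clipped to the sphere. Three small conventions are fixed and tested:
ties at exactly the threshold are *included*; when several voxels attain
SUVmax the first in lexicographic index order anchors the component; and
the component is clipped to the seed sphere rather than allowed to grow
beyond it (the connectivity restriction is what keeps background-gland
voxels above threshold from merging into the VOI). Extraction *fails* —
with an empty mask and a machine-readable status — when the mean SUV over a
user-supplied background region reaches the threshold, the situation in
which background mammary-gland uptake exceeds 40% of the lesion SUVmax. A
paired analysis drops any lesion that fails in either modality, and the
extraction report records per-lesion, per-modality statuses and exclusion
reasons.

Seed spheres are specified in millimeters, not voxel indices, so a single
seed addresses both modality grids of the same lesion. The sphere radius is
a required input: the clinical workflow it mirrors does not define it
algorithmically, and the cohort driver derives it from the known phantom
geometry.

## The feature engine

In-mask SUVs are quantized to `G = 64` gray levels over the in-mask range
(fixed bin number): `level = min(G, floor((v - min) / (max - min) * G) + 1)`,
with a zero-range lesion mapping entirely to level 1. Out-of-mask voxels
never enter any matrix. Thirty-eight texture features are computed:

* **Histogram (5).** SDhist, skewness and kurtosis are moments of the raw
  in-mask SUVs (kurtosis is non-excess — a normal distribution scores 3 —
  switchable to excess); Energy and Entropy come from the 64-bin histogram
  probabilities, entropies throughout in bits (log base 2).
* **GLCM (6).** Symmetric co-occurrences over the 13 unique 3D directions
  at Chebyshev distance 1, merged across directions before normalization;
  Haralick homogeneity, energy, correlation, contrast, entropy,
  dissimilarity. Correlation of a zero-variance (single-level) lesion is
  defined as 1: a perfectly predictable texture.
* **GLRLM (11).** Maximal equal-level runs along the same 13 directions,
  merged into one matrix; Galloway measures plus the low/high gray-level
  extensions; run percentage is runs / (voxels x directions).
* **GLZSM (11).** 26-connected equal-level zones; Thibault measures; zone
  percentage is zones / voxels.
* **NGLDM (3).** Amadasun–King coarseness, contrast and busyness from
  per-voxel absolute differences to the in-mask 26-neighborhood mean
  (center excluded, neighborhoods truncated at the mask edge). The
  coarseness denominator is guarded by epsilon = 1e-9, so a uniform lesion
  scores 1e9 (documented cap) with contrast and busyness 0.
* **NumVoxels and SUVsum** complete the 38; SUVmax, SUVmean, MTV (mask
  volume in mL) and TLG = MTV x SUVmean are reported alongside as
  conventional metrics.

Two genuinely open choices are exposed as configuration rather than silently
fixed. Direction handling defaults to *merging* counts across the 13
directions before feature computation — more robust than per-direction
feature averaging on small VOIs, where single directions can have almost no
pairs — with `aggregation = "average"` available for reproducing the other
convention. The GLCM offset distance defaults to 1 voxel. Offsets live in
index space, the common radiomics-engine convention; on anisotropic grids a
"neighbor" is therefore a grid neighbor, not an equidistant physical one,
and since the dbPET and wbPET grids differ, cross-modality feature
comparisons inherit that caveat.

Every matrix builder is pinned by an independent brute-force oracle
(exhaustive pair enumeration, run walking, recursive flood fill, direct
neighborhood loops) on hundreds of random masked volumes — agreement is
exact, not approximate — and the degenerate cases (uniform lesion, single
runs, singleton zones) are asserted against closed forms.

## Group statistics

Each feature is compared between the two groups of a dichotomy — Tis-1 vs
T2-4 (a T1 vs T2-4 boundary is also supported, as both appear in practice),
node-negative vs positive, Luminal A vs others, Ki67 below vs at-or-above
20% with unspecified excluded — by the Wilcoxon *rank-sum* test: exact null
for combined n of 25 or less without ties, normal approximation with
continuity and tie correction otherwise. The source workflow names the
signed-rank test for these contrasts, but the groups are independent, so
the rank-sum reading is the statistically coherent one; the paired
signed-rank variant is kept, as `compare_modalities()`, for its natural use
— contrasting the two modalities on the same lesions. Raw p-values are
reported cell by cell at alpha = 0.05 with no multiplicity correction,
matching the reporting convention of the tables this reproduces; a
Benjamini–Hochberg option exists but is off by default. Calibration is
demonstrated, not assumed: the suite checks exact agreement with full
permutation enumeration at small n and the empirical type-I error against
the binomial 99% interval under label permutation.

## Feature reduction and classification

PCA is fit per modality on the standardized 38 features (correlation-matrix
PCA). Standardization is what makes the Kaiser eigenvalue-greater-than-1
retention rule meaningful: each feature contributes exactly unit variance,
so a retained component explains more than any single feature, and the
eigenvalues sum to 38 (a tested trace identity). A logistic model on the
retained component scores (linear discriminant available) produces the
per-lesion score; the ROC operating point maximizes Youden's J, with
accuracy computed there; curves from the two modalities over the same
lesions are compared by the paired DeLong test. All reported AUCs are
apparent (in-sample) — the honest label for a small-cohort exploratory
design — and a leave-one-out mode exists as a clearly separate option.

```{r}
ext <- extract_cohort(cohort)
feats <- cohort_features(ext)
t3 <- table3_report(feats)
t3$table
autoplot(t3$results$dbPET$model)  # scree plot with the Kaiser line
```

## What the synthetic cohort does and does not show

The generator reproduces the *statistical skeleton* the analysis assumes:
paired volumes of a common ground truth at two resolutions, a size-driven
class signal, null labels, seedable stochasticity. Passing tests therefore
demonstrate that the machinery is correct and calibrated — matrices match
oracles, rank tests match enumeration, a pure size effect propagates to the
T-category AUC while the null N-category stays behind it. They do not
demonstrate clinical classification power: real lesions are not ellipsoids
with Gaussian textures, real noise is not additive white Gaussian, and real
labels correlate with uptake in ways no parameter here encodes.

Two quantitative findings from the suite deserve emphasis because they are
easy to assume away:

* **Kaiser retention can discard an isolated signal.** When exactly one
  standardized feature carries a class separation and the other 37 are
  independent noise, the informative direction has unit variance like
  everything else, so the retained components capture only part of it and
  the in-sample AUC lands well below the binormal ideal for the same
  separation. Texture features in practice are highly inter-correlated —
  the very premise of using PCA here — but the edge case bounds what the
  reduction step can promise.
* **Coarse-grid VOIs are edge-dominated.** On the wbPET grid a
  threshold-delineated lesion of realistic size is a few voxels across;
  most in-mask voxel pairs straddle the partial-volume ramp at the lesion
  boundary, which spans most of the in-mask intensity range after
  fixed-bin-number quantization. GLCM contrast on the coarse grid is
  therefore *inflated* relative to dbPET even though the blur demonstrably
  destroys intra-lesion variation (the in-lesion SD ordering holds
  essentially always). Resolution comparisons of texture magnitudes across
  grids should be read with that in mind.

## Numerical conventions, degenerate inputs, problem sizes

Entropies use log base 2; the NGLDM coarseness guard is 1e-9; a uniform
lesion yields the documented degenerate vector (histogram energy 1, entropy
0, GLCM homogeneity/energy/correlation 1, contrast 0, skewness 0, kurtosis
3) rather than NaNs; moment features require at least 2 voxels; GLCM
requires at least one in-mask pair and NGLDM at least one voxel with a
neighbor, otherwise they error with the feature family named. Volumes must
be finite, nonnegative, with positive header spacing — violations are
refused at the boundary, never repaired silently.

Test problem sizes are chosen to make each property decisive at desk scale:
oracle equivalence on 100 random 5x5x5 masked volumes, calibration over 250
label permutations at n = 50, AUC recovery at n = 400, and the end-to-end
ordering property on 50 seeded replicates of a 40-lesion two-class cohort
in a 32 mm field of view. The default 44-lesion cohort used by the
reproduction script runs the full pipeline — simulation through DeLong —
in well under a minute on one core.
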