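# pettex

Texture analysis of dual-resolution breast PET images: a reproducible R
pipeline for asking whether the texture features of a high-resolution
**dedicated breast PET** (dbPET: 0.78 × 0.78 × 2.34 mm voxels, 1.17 mm FWHM
post-smoothing) classify breast-tumor characteristics better than those of a
**whole-body PET/CT** (4.11 × 4.11 × 5 mm voxels, 5 mm FWHM) — the question a
radiomics group faces when both scanners image the same lesion.

The package is written for imaging scientists who want the whole chain as
tested, composable functions: phantom simulation of paired acquisitions,
threshold-based lesion delineation, a 38-feature texture engine, per-feature
group statistics, and PCA-reduced ROC classification.

## What it computes

* **Paired synthetic cohorts.** Ellipsoidal lesions with a seedable Gaussian
  random-field heterogeneity on a fine 0.5 mm grid, imaged by each modality
  profile as Gaussian PSF blur → overlap-weighted rebinning to the scanner
  grid (the partial-volume step) → additive noise. Both modality volumes of a
  lesion derive from the same ground truth. Labels (T-category, N-category,
  molecular subtype, Ki67) emulate a 44-lesion clinical cohort; lesion size
  tracks T-category, the other labels are null by construction.
* **Delineation.** The VOI is the 26-connected component of voxels at or
  above 40% of SUVmax inside a spherical seed, anchored at the hottest voxel;
  extraction fails when the background-region mean reaches the threshold
  (background gland uptake ≥ 40% of SUVmax), and a paired analysis drops
  lesions failing in either modality.
* **Features.** SUVs quantized to 64 gray levels over the in-mask range;
  5 histogram features (SD, skewness, kurtosis, energy, entropy), 31 matrix
  features from GLCM (6, Haralick), GLRLM (11, Galloway + extensions), GLZSM
  (11, Thibault), NGLDM (3, Amadasun–King), plus NumVoxels and SUVsum — 38 in
  all — alongside SUVmax, SUVmean, MTV (VOI volume in mL) and
  TLG = MTV × SUVmean. Matrices use the 13 unique 3D directions at Chebyshev
  distance 1, merged before normalization; every matrix is pinned by
  brute-force oracle tests.
* **Statistics.** Wilcoxon rank-sum per (feature × dichotomy × modality) cell
  with exact small-sample nulls, α = 0.05, no multiplicity correction by
  default (Benjamini–Hochberg optional); paired signed-rank for
  dbPET-vs-wbPET contrasts.
* **Classification.** Per-modality correlation-matrix PCA with the Kaiser
  eigenvalue > 1 retention rule, logistic model on retained component scores,
  ROC with the Youden operating point, and the paired DeLong test between the
  two modalities' curves.

## Worked example

```r
library(pettex)

design <- cohort_design(n_lesions = 12, seed = 42,
                        classes = c(T1 = 0.5, T2 = 0.5),
                        fov_mm = c(40, 40, 40))
cohort <- generate_cohort(design)      # paired dbPET + wbPET volumes
ext    <- extract_cohort(cohort)       # 40%-of-SUVmax delineation
head(ext$report, 4)
#>   lesion_id modality status    suvmax threshold n_voxels excluded
#> 1 L001      dbPET    extracted  13.0       5.21      647 FALSE
#> 2 L001      wbPET    extracted   6.82      2.73       20 FALSE
#> 3 L002      dbPET    extracted   9.96      3.99      861 FALSE
#> 4 L002      wbPET    extracted   6.47      2.59       22 FALSE
```

The report shows the resolution story already: the same lesion that spans
647 dbPET voxels occupies 20 wbPET voxels, and partial-volume averaging has
dropped its SUVmax from 13.0 to 6.8.

```r
feats <- cohort_features(ext)          # 38 texture + 4 conventional per row
fit   <- fit_pca(dplyr::filter(feats, modality == "dbPET"))
glance(fit)
#>   n_features n_obs n_retained explained_fraction eigenvalue_sum
#> 1         38    12          4              0.966           38.0

t3 <- table3_report(feats)
t3$table[, c("modality", "characteristic", "auc", "accuracy")]
#>   modality characteristic      auc accuracy
#> 1 dbPET    T-category        1        1
#> 2 dbPET    N-category        0.861    0.833
#> ...
compare_roc(t3$results$dbPET$rocs$T_category,
            t3$results$wbPET$rocs$T_category)
#>   auc_a auc_b auc_diff p_value  n
#> 1     1     1        0       1 12
```

Four principal components carry 96.6% of the texture variance; the
size-driven T-category is classified perfectly by both modalities (the
cohort was built that way), the null N-category hovers near chance plus
in-sample optimism, and the paired DeLong test finds no modality difference.
AUCs are apparent (in-sample) by design; `score_and_classify(..., cv = TRUE)`
gives leave-one-out scores.

`run_pipeline()` (or `inst/scripts/pettex-pipeline.R` from a shell) chains
every stage from a YAML config into CSV reports plus a JSON manifest with
per-lesion exclusion reasons and reproducibility hashes.

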