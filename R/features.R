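# The 38-feature inventory and its formulas.
#
# Five histogram features, 31 matrix features (6 GLCM, 11 GLRLM, 11 GLZSM,
# 3 NGLDM) and two size/intensity counts (NumVoxels, SUVsum) make up the 38
# texture features; SUVmax, SUVmean, MTV and TLG are the conventional
# metrics. Entropies use log base 2. Formulas are the standard
# Haralick / Galloway (extended) / Thibault / Amadasun-King definitions,
# written out below and pinned by brute-force oracle tests.

#' Feature name inventories
#'
#' `texture_feature_names()` returns the 38 texture feature names in report
#' order; `conventional_metric_names()` the four conventional SUV metrics.
#'
#' @return Character vector of feature names.
#' @export
texture_feature_names <- function() {
  c("NumVoxels", "SUVsum",
    "SDhist", "Skewness", "Kurtosis", "Energy_Hist", "Entropy_Hist",
    "Homogeneity_GLCM", "Energy_GLCM", "Correlation_GLCM", "Contrast_GLCM",
    "Entropy_GLCM", "Dissimilarity_GLCM",
    "SRE", "LRE", "LGRE", "HGRE", "SRLGE", "SRHGE", "LRLGE", "LRHGE",
    "GLNUr", "RLNU", "RP",
    "SZE", "LZE", "LGZE", "HGZE", "SZLGE", "SZHGE", "LZLGE", "LZHGE",
    "GLNUz", "ZSNU", "ZP",
    "Coarseness_NGLDM", "Contrast_NGLDM", "Busyness_NGLDM")
}

#' @rdname texture_feature_names
#' @export
conventional_metric_names <- function() {
  c("SUVmax", "SUVmean", "MTV", "TLG")
}

#' Conventional SUV metrics of a delineated lesion
#'
#' MTV is the VOI volume (voxel count times voxel volume, reported in mL);
#' SUVmean is the average SUV over all VOI voxels; TLG = MTV x SUVmean.
#'
#' @param volume An [suv_volume()].
#' @param voi An extracted `lesion_voi`.
#' @return A named list: `SUVmax`, `SUVmean`, `MTV` (mL), `TLG` (mL * SUV),
#'   `NumVoxels`, `SUVsum`.
#' @export
conventional_metrics <- function(volume, voi) {
  stopifnot(inherits(volume, "suv_volume"), inherits(voi, "lesion_voi"))
  if (voi$status != "extracted" || voi$n_voxels == 0) {
    stop_pettex("lesion mask is empty (status `%s`)", voi$status)
  }
  suv <- volume$values[voi$mask]
  n <- length(suv)
  mtv_ml <- n * prod(volume$spacing_mm) / 1000
  suvmean <- mean(suv)
  list(SUVmax = voi$suvmax, SUVmean = suvmean, MTV = mtv_ml,
       TLG = mtv_ml * suvmean, NumVoxels = n, SUVsum = sum(suv))
}

#' Histogram features
#'
#' `SDhist`, `Skewness` and `Kurtosis` are the sample SD and the standardized
#' third and fourth moments of the raw in-mask SUVs (kurtosis non-excess by
#' default, i.e. a normal distribution scores 3); `Energy_Hist` and
#' `Entropy_Hist` come from the G-level histogram probabilities:
#' `Energy = sum(p^2)`, `Entropy = -sum(p * log2(p))`.
#'
#' A lesion with zero SUV spread has `SDhist = 0`, `Skewness = 0` and
#' `Kurtosis = 3` (0 in the excess convention) by definition.
#'
#' @param q A `quantized_lesion`.
#' @param kurtosis_excess Use the excess convention (normal scores 0)?
#' @return Named list of the five histogram features.
#' @export
histogram_features <- function(q, kurtosis_excess = FALSE) {
  x <- q$raw_suv
  if (length(x) < 2) stop_pettex("histogram moment features need >= 2 voxels")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 > 0) {
    skew <- mean((x - m)^3) / m2^1.5
    kurt <- mean((x - m)^4) / m2^2
  } else {
    skew <- 0
    kurt <- 3
  }
  if (kurtosis_excess) kurt <- kurt - 3
  p <- tabulate(q$levels[!is.na(q$levels)], nbins = q$G) / q$n_voxels
  p <- p[p > 0]
  list(SDhist = sd(x), Skewness = skew, Kurtosis = kurt,
       Energy_Hist = sum(p^2), Entropy_Hist = -sum(p * log2(p)))
}

glcm_features_from_matrix <- function(counts) {
  tot <- sum(counts)
  if (tot == 0) stop_pettex("GLCM has no in-mask voxel pairs")
  P <- counts / tot
  G <- nrow(P)
  i <- matrix(seq_len(G), G, G)
  j <- t(i)
  pi_ <- rowSums(P)
  mu <- sum(seq_len(G) * pi_)
  sig2 <- sum((seq_len(G) - mu)^2 * pi_)
  pos <- P > 0
  list(
    Homogeneity_GLCM = sum(P / (1 + abs(i - j))),
    Energy_GLCM = sum(P^2),
    Correlation_GLCM = if (sig2 > 0) (sum(i * j * P) - mu^2) / sig2 else 1,
    Contrast_GLCM = sum((i - j)^2 * P),
    Entropy_GLCM = -sum(P[pos] * log2(P[pos])),
    Dissimilarity_GLCM = sum(abs(i - j) * P)
  )
}

#' GLCM features
#'
#' Six Haralick features from the symmetric co-occurrence matrix:
#' homogeneity `sum(P / (1 + |i - j|))`, energy `sum(P^2)`, correlation
#' `(sum(i j P) - mu^2) / sigma^2` (defined as 1 when the marginal variance is
#' zero), contrast `sum((i - j)^2 P)`, entropy `-sum(P log2 P)`, and
#' dissimilarity `sum(|i - j| P)`.
#'
#' @inheritParams glcm_matrix
#' @param aggregation `"merge"` (sum counts across directions before
#'   normalizing; the default) or `"average"` (average per-direction feature
#'   values).
#' @return Named list of the six GLCM features.
#' @export
glcm_features <- function(q, directions = offsets13(), distance = 1L,
                          aggregation = c("merge", "average")) {
  aggregation <- match.arg(aggregation)
  if (aggregation == "merge") {
    return(glcm_features_from_matrix(glcm_matrix(q, directions, distance)))
  }
  per_dir <- lapply(seq_len(nrow(directions)), function(r) {
    m <- glcm_matrix(q, directions[r, , drop = FALSE], distance)
    if (sum(m) == 0) NULL else glcm_features_from_matrix(m)
  })
  per_dir <- purrr::compact(per_dir)
  if (length(per_dir) == 0) stop_pettex("GLCM has no in-mask voxel pairs")
  purrr::map(purrr::transpose(per_dir), ~ mean(unlist(.x)))
}

rl_features_from_matrix <- function(R, n_voxels, n_directions,
                                    flavor = c("run", "zone")) {
  flavor <- match.arg(flavor)
  nr <- sum(R)
  i <- matrix(seq_len(nrow(R)), nrow(R), ncol(R))
  j <- t(matrix(seq_len(ncol(R)), ncol(R), nrow(R)))
  f <- list(
    sum(R / j^2) / nr,                 # SRE / SZE
    sum(R * j^2) / nr,                 # LRE / LZE
    sum(R / i^2) / nr,                 # LGRE / LGZE
    sum(R * i^2) / nr,                 # HGRE / HGZE
    sum(R / (i^2 * j^2)) / nr,         # SRLGE / SZLGE
    sum(R * i^2 / j^2) / nr,           # SRHGE / SZHGE
    sum(R * j^2 / i^2) / nr,           # LRLGE / LZLGE
    sum(R * i^2 * j^2) / nr,           # LRHGE / LZHGE
    sum(rowSums(R)^2) / nr,            # GLNUr / GLNUz
    sum(colSums(R)^2) / nr,            # RLNU / ZSNU
    nr / (n_voxels * n_directions)     # RP / ZP
  )
  names(f) <- if (flavor == "run") {
    c("SRE", "LRE", "LGRE", "HGRE", "SRLGE", "SRHGE", "LRLGE", "LRHGE",
      "GLNUr", "RLNU", "RP")
  } else {
    c("SZE", "LZE", "LGZE", "HGZE", "SZLGE", "SZHGE", "LZLGE", "LZHGE",
      "GLNUz", "ZSNU", "ZP")
  }
  f
}

#' GLRLM features
#'
#' Eleven run-length features (Galloway plus the low/high gray-level
#' extensions) from runs merged across directions; the run percentage is
#' `RP = total runs / (voxels x directions)`.
#'
#' @inheritParams glcm_features
#' @return Named list of the 11 GLRLM features.
#' @export
glrlm_features <- function(q, directions = offsets13(),
                           aggregation = c("merge", "average")) {
  aggregation <- match.arg(aggregation)
  if (aggregation == "merge") {
    R <- glrlm_matrix(q, directions)
    return(rl_features_from_matrix(R, q$n_voxels, nrow(directions), "run"))
  }
  per_dir <- lapply(seq_len(nrow(directions)), function(r) {
    R <- glrlm_matrix(q, directions[r, , drop = FALSE])
    rl_features_from_matrix(R, q$n_voxels, 1L, "run")
  })
  purrr::map(purrr::transpose(per_dir), ~ mean(unlist(.x)))
}

#' GLZSM features
#'
#' Eleven zone-size features (Thibault) over 26-connected equal-gray-level
#' zones; the zone percentage is `ZP = zones / voxels`.
#'
#' @param q A `quantized_lesion`.
#' @return Named list of the 11 GLZSM features.
#' @export
glzsm_features <- function(q) {
  Z <- glzsm_matrix(q)
  rl_features_from_matrix(Z, q$n_voxels, 1L, "zone")
}

#' NGLDM features
#'
#' Amadasun-King coarseness, contrast and busyness from the neighborhood
#' gray-level difference accumulators, with occupancy probabilities
#' `p_i = N_i / N` over the `N` voxels that have at least one in-mask
#' neighbor. The coarseness denominator is guarded by `epsilon`; a perfectly
#' uniform lesion scores `Coarseness = 1 / epsilon`, `Contrast = 0`,
#' `Busyness = 0` by the zero-denominator convention.
#'
#' @param q A `quantized_lesion`.
#' @param epsilon Denominator guard (default 1e-9).
#' @return Named list of the three NGLDM features.
#' @export
ngldm_features <- function(q, epsilon = 1e-9) {
  m <- ngldm_matrix(q)
  p <- m$n / m$n_valid
  psd <- sum(p * m$s)
  lv <- which(p > 0)
  ng <- length(lv)
  contrast <- if (ng > 1) {
    cross <- outer(lv, lv, function(a, b) (a - b)^2)
    (sum(outer(p[lv], p[lv]) * cross) / (ng * (ng - 1))) * (sum(m$s) / m$n_valid)
  } else 0
  denom <- 0
  if (ng > 1) {
    ip <- lv * p[lv]
    denom <- sum(abs(outer(ip, ip, "-")))
  }
  busy <- if (denom > 0) psd / denom else 0
  list(Coarseness_NGLDM = 1 / (epsilon + psd),
       Contrast_NGLDM = contrast,
       Busyness_NGLDM = busy)
}

#' Full feature vector of one lesion in one modality
#'
#' Quantizes the delineated lesion to `G` gray levels and computes the 38
#' texture features plus the four conventional SUV metrics as one tidy row.
#'
#' @param volume An [suv_volume()].
#' @param voi An extracted `lesion_voi`.
#' @param G Number of gray levels (default 64).
#' @param directions Direction offsets for GLCM/GLRLM.
#' @param glcm_distance GLCM offset distance in voxels.
#' @param aggregation Direction aggregation for GLCM/GLRLM (`"merge"` or
#'   `"average"`).
#' @param kurtosis_excess Kurtosis convention, see [histogram_features()].
#' @return A one-row tibble: `lesion_id`, `modality`, the four conventional
#'   metrics, then the 38 texture features in report order.
#' @export
feature_vector <- function(volume, voi, G = 64L, directions = offsets13(),
                           glcm_distance = 1L,
                           aggregation = c("merge", "average"),
                           kurtosis_excess = FALSE) {
  aggregation <- match.arg(aggregation)
  with_family <- function(family, expr) {
    tryCatch(expr, error = function(e) {
      stop_pettex("%s features failed for %s/%s: %s", family,
                  volume$lesion_id, volume$modality, conditionMessage(e))
    })
  }
  conv <- with_family("conventional", conventional_metrics(volume, voi))
  q <- quantize(volume, voi, G)
  feats <- c(
    list(NumVoxels = conv$NumVoxels, SUVsum = conv$SUVsum),
    with_family("histogram", histogram_features(q, kurtosis_excess)),
    with_family("GLCM", glcm_features(q, directions, glcm_distance, aggregation)),
    with_family("GLRLM", glrlm_features(q, directions, aggregation)),
    with_family("GLZSM", glzsm_features(q)),
    with_family("NGLDM", ngldm_features(q))
  )
  out <- c(list(lesion_id = volume$lesion_id, modality = volume$modality,
                SUVmax = conv$SUVmax, SUVmean = conv$SUVmean,
                MTV = conv$MTV, TLG = conv$TLG),
           feats[texture_feature_names()])
  as_tibble(out)
}

#' Feature table of a whole extracted cohort
#'
#' Runs [feature_vector()] on every retained (lesion, modality) pair of a
#' [extract_cohort()] result and joins the cohort labels, yielding the
#' lesions-by-features table that the statistics and classification stages
#' consume. Lesions excluded by the extraction report are dropped.
#'
#' @param extraction A `pet_extraction`.
#' @inheritParams feature_vector
#' @return A tibble with one row per (lesion, modality).
#' @export
cohort_features <- function(extraction, G = 64L, directions = offsets13(),
                            glcm_distance = 1L,
                            aggregation = c("merge", "average"),
                            kurtosis_excess = FALSE) {
  stopifnot(inherits(extraction, "pet_extraction"))
  aggregation <- match.arg(aggregation)
  report <- extraction$report
  retained <- setdiff(unique(report$lesion_id),
                      unique(report$lesion_id[report$excluded]))
  if (length(retained) == 0) stop_pettex("no lesion was extractable in every modality")
  rows <- purrr::map_dfr(retained, function(id) {
    les <- extraction$cohort$lesions[[id]]
    purrr::map_dfr(names(les$volumes), function(mod) {
      feature_vector(les$volumes[[mod]], extraction$vois[[id]][[mod]],
                     G = G, directions = directions,
                     glcm_distance = glcm_distance, aggregation = aggregation,
                     kurtosis_excess = kurtosis_excess)
    })
  })
  dplyr::left_join(rows, extraction$cohort$labels, by = "lesion_id")
}

#' Write / read a cohort feature table as CSV
#'
#' Columns are ordered as identifiers, labels, conventional metrics, then the
#' 38 texture features in report order. Duplicate (lesion_id, modality) rows
#' are refused.
#'
#' @param cohort A cohort feature tibble (see [cohort_features()]).
#' @param path CSV path.
#' @return `read_feature_table()` returns the tibble.
#' @export
write_feature_table <- function(cohort, path) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0) {
    stop_pettex("cohort feature table is empty")
  }
  key <- paste(cohort$lesion_id, cohort$modality)
  if (anyDuplicated(key)) {
    stop_pettex("duplicate (lesion_id, modality) rows: %s",
                paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  lead <- c("lesion_id", "modality",
            intersect(names(label_vocab), names(cohort)),
            conventional_metric_names(), texture_feature_names())
  cols <- c(intersect(lead, names(cohort)), setdiff(names(cohort), lead))
  utils::write.csv(cohort[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  as_tibble(utils::read.csv(path, check.names = FALSE,
                            stringsAsFactors = FALSE))
}
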