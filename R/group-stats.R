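# Per-feature two-group comparisons across tumor characteristics.

#' Two-group dichotomy of a tumor characteristic
#'
#' Maps the levels of one label column to two groups (group1 is treated as
#' the positive class in ROC analyses); levels in neither set are excluded
#' from the comparison.
#'
#' @param name Short identifier of the dichotomy.
#' @param characteristic Display name of the tumor characteristic.
#' @param label_col Label column of the cohort table.
#' @param group0,group1 Character vectors of levels forming the two groups.
#' @param contrast Display string (e.g. `"Tis-1 vs. T2-4"`).
#' @return A `dichotomy` object.
#' @export
dichotomy <- function(name, characteristic, label_col, group0, group1,
                      contrast = paste(paste(group0, collapse = "/"), "vs.",
                                       paste(group1, collapse = "/"))) {
  if (length(intersect(group0, group1)) > 0) {
    stop_pettex("groups of dichotomy `%s` overlap", name)
  }
  structure(list(name = name, characteristic = characteristic,
                 label_col = label_col, group0 = group0, group1 = group1,
                 contrast = contrast),
            class = "dichotomy")
}

apply_dichotomy <- function(d, labels) {
  out <- rep(NA_integer_, length(labels))
  out[labels %in% d$group0] <- 0L
  out[labels %in% d$group1] <- 1L
  out
}

#' Default tumor-characteristic dichotomies
#'
#' The four standard contrasts: T-category (Tis-1 vs. T2-4 by default, or
#' T1 vs. T2-4 via `t_split = "t1"` — both boundaries appear in the
#' literature), N-category (negative vs. positive), molecular subtype
#' (Luminal A vs. others), and Ki67 level (<20% vs. >=20%; unspecified
#' excluded).
#'
#' @param t_split `"tis1"` (default) or `"t1"`.
#' @return Named list of [dichotomy()] objects.
#' @export
default_dichotomies <- function(t_split = c("tis1", "t1")) {
  t_split <- match.arg(t_split)
  t_group0 <- if (t_split == "tis1") c("Tis", "T1") else "T1"
  list(
    T_category = dichotomy("T_category", "T-category", "T_category",
                           group0 = t_group0, group1 = c("T2", "T3", "T4"),
                           contrast = if (t_split == "tis1") "Tis-1 vs. T2-4"
                                      else "T1 vs. T2-4"),
    N_category = dichotomy("N_category", "N-category", "N_category",
                           group0 = "N0", group1 = c("N1", "N2", "N3"),
                           contrast = "Negative vs. Positive"),
    subtype = dichotomy("subtype", "Molecular subtype", "subtype",
                        group0 = "Luminal A",
                        group1 = c("Luminal B/HER2-", "Luminal B/HER2+",
                                   "HER2", "Triple-negative"),
                        contrast = "Luminal A vs. Others"),
    ki67 = dichotomy("ki67", "Ki67 level", "ki67",
                     group0 = "<20%", group1 = ">=20%",
                     contrast = "<20% vs. >=20%")
  )
}

#' Compare one feature between two groups
#'
#' Wilcoxon rank-sum comparison of one feature between the two groups of a
#' dichotomy, within one modality. The exact null distribution is used for
#' combined n <= 25 without ties; otherwise the normal approximation with
#' continuity and tie correction.
#'
#' @param cohort Cohort feature tibble (see [cohort_features()]).
#' @param feature Feature column name.
#' @param dich A [dichotomy()].
#' @param modality Modality to subset to (`NULL` = use all rows).
#' @param alpha Significance level for the flag (default 0.05).
#' @return One-row tibble: group sizes, medians, `p_value`, `significant`.
#' @export
compare_feature <- function(cohort, feature, dich, modality = NULL,
                            alpha = 0.05) {
  stopifnot(inherits(dich, "dichotomy"))
  if (!feature %in% names(cohort)) stop_pettex("unknown feature `%s`", feature)
  rows <- cohort
  if (!is.null(modality)) rows <- rows[rows$modality == modality, ]
  grp <- apply_dichotomy(dich, rows[[dich$label_col]])
  x0 <- rows[[feature]][!is.na(grp) & grp == 0L]
  x1 <- rows[[feature]][!is.na(grp) & grp == 1L]
  if (length(x0) < 2 || length(x1) < 2) {
    stop_pettex("dichotomy `%s` leaves a group with fewer than 2 observations",
                dich$name)
  }
  n <- length(x0) + length(x1)
  p <- suppressWarnings(
    wilcox.test(x0, x1, exact = n <= 25, correct = TRUE)$p.value
  )
  tibble(feature = feature, dichotomy = dich$name,
         characteristic = dich$characteristic, contrast = dich$contrast,
         modality = modality %||% NA_character_,
         n0 = length(x0), n1 = length(x1),
         median0 = median(x0), median1 = median(x1),
         p_value = p, significant = p < alpha)
}

#' Paired modality contrast of one feature
#'
#' Wilcoxon signed-rank test of one feature between two modalities over the
#' same lesions (paired by lesion id).
#'
#' @param cohort Cohort feature tibble.
#' @param feature Feature column name.
#' @param modalities Length-2 character vector of modality labels.
#' @return One-row tibble with the paired `p_value`.
#' @export
compare_modalities <- function(cohort, feature,
                               modalities = c("dbPET", "wbPET")) {
  a <- cohort[cohort$modality == modalities[1], c("lesion_id", feature)]
  b <- cohort[cohort$modality == modalities[2], c("lesion_id", feature)]
  m <- dplyr::inner_join(a, b, by = "lesion_id", suffix = c("_a", "_b"))
  if (nrow(m) < 2) stop_pettex("fewer than 2 paired lesions")
  p <- suppressWarnings(
    wilcox.test(m[[paste0(feature, "_a")]], m[[paste0(feature, "_b")]],
                paired = TRUE)$p.value
  )
  tibble(feature = feature, modality_a = modalities[1],
         modality_b = modalities[2], n = nrow(m), p_value = p)
}

#' Feature-by-dichotomy association matrix
#'
#' Runs [compare_feature()] for every (feature, dichotomy, modality) cell.
#' Cells whose preconditions fail (a group with fewer than 2 observations
#' after label filtering) are kept with `computable = FALSE` rather than
#' erroring. Raw p-values are reported per cell (no multiple-testing
#' correction, matching the convention of reporting each cell at alpha =
#' 0.05); Benjamini-Hochberg adjustment is available via `adjust = "BH"`.
#'
#' @param cohort Cohort feature tibble.
#' @param dichotomies Named list of [dichotomy()] objects.
#' @param features Feature columns to test (default: the 38 texture features).
#' @param alpha Significance level.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A long tibble with one row per cell; see also [table2_style()].
#' @export
association_table <- function(cohort, dichotomies = default_dichotomies(),
                              features = texture_feature_names(),
                              alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (nrow(cohort) == 0) stop_pettex("empty cohort")
  modalities <- unique(cohort$modality)
  grid <- tidyr::expand_grid(modality = modalities,
                             dich = unname(dichotomies),
                             feature = features)
  out <- purrr::pmap_dfr(grid, function(modality, dich, feature) {
    tryCatch(
      dplyr::mutate(
        compare_feature(cohort, feature, dich, modality, alpha),
        computable = TRUE),
      error = function(e) {
        tibble(feature = feature, dichotomy = dich$name,
               characteristic = dich$characteristic,
               contrast = dich$contrast, modality = modality,
               n0 = NA_integer_, n1 = NA_integer_,
               median0 = NA_real_, median1 = NA_real_,
               p_value = NA_real_, significant = NA, computable = FALSE)
      })
  })
  if (adjust == "BH") {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
    out$significant <- !is.na(out$p_adjusted) & out$p_adjusted < alpha
  }
  out
}

#' @describeIn association_table The same matrix restricted to the
#'   conventional metrics SUVmax, MTV and TLG over all four dichotomies.
#' @export
conventional_association_table <- function(cohort,
                                           dichotomies = default_dichotomies(),
                                           alpha = 0.05) {
  association_table(cohort, dichotomies,
                    features = c("SUVmax", "MTV", "TLG"), alpha = alpha)
}

#' Pivot an association matrix to the wide report layout
#'
#' One row per feature, one column per (modality, dichotomy) pair, cells
#' holding p-values (NA where not computable).
#'
#' @param assoc Output of [association_table()].
#' @return A wide tibble.
#' @export
table2_style <- function(assoc) {
  tidyr::pivot_wider(
    assoc[, c("feature", "modality", "dichotomy", "p_value")],
    names_from = c("modality", "dichotomy"), values_from = "p_value"
  )
}

#' Tile plot of an association matrix
#'
#' @param assoc Output of [association_table()].
#' @param alpha Significance level used for the outline.
#' @return A ggplot object.
#' @export
plot_association <- function(assoc, alpha = 0.05) {
  assoc$cell <- paste(assoc$modality, assoc$contrast, sep = "\n")
  ggplot2::ggplot(assoc,
                  ggplot2::aes(x = .data$cell,
                               y = factor(.data$feature,
                                          levels = rev(unique(.data$feature))),
                               fill = -log10(.data$p_value))) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::geom_tile(data = assoc[!is.na(assoc$significant) & assoc$significant, ],
                       fill = NA, color = "black", linewidth = 0.4) +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = "-log10 p") +
    ggplot2::theme_minimal(base_size = 9)
}
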