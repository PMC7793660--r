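# ROC classification of tumor-characteristic dichotomies from retained
# principal-component scores, and paired comparison of two modalities' curves.

#' Classify a dichotomy from retained PC scores and build its ROC curve
#'
#' Projects the cohort onto the retained components of a fitted PCA, fits a
#' logistic model (or linear discriminant) of the dichotomy on the component
#' scores, and evaluates the per-lesion score by ROC analysis. The operating
#' point maximizes Youden's J (sensitivity + specificity - 1); accuracy is
#' computed at that point. AUCs are apparent (in-sample), matching a
#' small-cohort exploratory design; `cv = TRUE` switches to leave-one-out
#' scores as a clearly separate, honest-error mode.
#'
#' @param model A `pet_pca` fitted on the same modality's features.
#' @param cohort Cohort feature tibble (typically one modality).
#' @param dich A [dichotomy()].
#' @param classifier `"logistic"` (default) or `"lda"`.
#' @param cv Use leave-one-out cross-validated scores instead of in-sample
#'   fitted scores.
#' @return A `roc_result`: `auc`, `sensitivity`, `specificity`, `accuracy`,
#'   `threshold`, `curve` (tibble of ROC points), scores, labels and lesion
#'   ids.
#' @export
score_and_classify <- function(model, cohort, dich,
                               classifier = c("logistic", "lda"), cv = FALSE) {
  stopifnot(inherits(model, "pet_pca"), inherits(dich, "dichotomy"))
  classifier <- match.arg(classifier)
  grp <- apply_dichotomy(dich, cohort[[dich$label_col]])
  keep <- !is.na(grp)
  rows <- cohort[keep, ]
  y <- grp[keep]
  if (length(unique(y)) < 2) {
    stop_pettex("dichotomy `%s`: both classes must be present", dich$name)
  }
  S <- pca_scores(model, rows)
  score_fun <- function(train_idx, test_idx) {
    df_train <- data.frame(y = y[train_idx], S[train_idx, , drop = FALSE])
    df_test <- data.frame(S[test_idx, , drop = FALSE])
    if (classifier == "logistic") {
      fit <- suppressWarnings(glm(y ~ ., data = df_train, family = binomial()))
      as.numeric(suppressWarnings(predict(fit, df_test, type = "response")))
    } else {
      fit <- MASS::lda(y ~ ., data = df_train)
      as.numeric(predict(fit, df_test)$posterior[, "1"])
    }
  }
  n <- length(y)
  scores <- if (cv) {
    vapply(seq_len(n), function(i) score_fun(setdiff(seq_len(n), i), i), numeric(1))
  } else {
    score_fun(seq_len(n), seq_len(n))
  }
  ids <- if ("lesion_id" %in% names(rows)) rows$lesion_id else NULL
  roc_from_scores(y, scores, lesion_id = ids, dichotomy = dich, model = model)
}

# Build a roc_result from labels (0/1) and scores.
roc_from_scores <- function(y, scores, lesion_id = NULL, dichotomy = NULL,
                            model = NULL) {
  roc <- pROC::roc(response = y, predictor = scores, levels = c(0, 1),
                   direction = "<", quiet = TRUE)
  best <- pROC::coords(roc, "best", best.method = "youden",
                       ret = c("threshold", "sensitivity", "specificity",
                               "accuracy"),
                       transpose = FALSE)
  best <- best[1, , drop = FALSE]  # deterministic tie-break: first best point
  curve <- tibble(
    threshold = roc$thresholds,
    sensitivity = roc$sensitivities,
    specificity = roc$specificities
  )
  structure(
    list(auc = as.numeric(pROC::auc(roc)),
         sensitivity = best$sensitivity, specificity = best$specificity,
         accuracy = best$accuracy, threshold = best$threshold,
         curve = curve, scores = as.numeric(scores), labels = as.integer(y),
         lesion_id = lesion_id, dichotomy = dichotomy,
         n_retained = if (!is.null(model)) model$n_retained else NA_integer_,
         roc = roc),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "<roc_result>%s AUC=%.3f sens=%.2f spec=%.2f acc=%.2f (n=%d)\n",
    if (!is.null(x$dichotomy)) paste0(" ", x$dichotomy$contrast) else "",
    x$auc, x$sensitivity, x$specificity, x$accuracy, length(x$labels)))
  invisible(x)
}

#' @rdname tidy.pet_pca
#' @method glance roc_result
#' @export
glance.roc_result <- function(x, ...) {
  tibble(auc = x$auc, sensitivity = x$sensitivity,
         specificity = x$specificity, accuracy = x$accuracy,
         threshold = x$threshold, n = length(x$labels))
}

#' ROC curve of one classification result
#'
#' @param object A `roc_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(1 - .data$specificity, .data$sensitivity)) +
    ggplot2::geom_path() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  subtitle = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Overlay the ROC curves of several results
#'
#' @param results Named list of `roc_result` objects (names become the
#'   legend, e.g. modalities).
#' @return A ggplot object.
#' @export
plot_roc_overlay <- function(results) {
  df <- purrr::imap_dfr(results, function(r, nm) {
    dplyr::mutate(r$curve, which = sprintf("%s (AUC %.2f)", nm, r$auc))
  })
  ggplot2::ggplot(df, ggplot2::aes(1 - .data$specificity, .data$sensitivity,
                                   color = .data$which)) +
    ggplot2::geom_path() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity", color = NULL) +
    ggplot2::theme_minimal()
}

#' Paired DeLong comparison of two modalities' ROC curves
#'
#' Two-sided DeLong test of the AUC difference between two `roc_result`
#' objects computed on the same lesions (paired by lesion id and identical
#' labels).
#'
#' @param result_a,result_b `roc_result` objects over the same lesion set.
#' @return One-row tibble: the two AUCs, their difference and the paired
#'   `p_value`.
#' @export
compare_roc <- function(result_a, result_b) {
  stopifnot(inherits(result_a, "roc_result"), inherits(result_b, "roc_result"))
  if (!is.null(result_a$lesion_id) || !is.null(result_b$lesion_id)) {
    if (is.null(result_a$lesion_id) || is.null(result_b$lesion_id) ||
        !identical(result_a$lesion_id, result_b$lesion_id)) {
      stop_pettex("the two ROC results cover different lesion sets")
    }
  }
  if (!identical(result_a$labels, result_b$labels)) {
    stop_pettex("the two ROC results have different labels")
  }
  p <- if (isTRUE(all.equal(result_a$scores, result_b$scores))) {
    1  # identical score vectors: zero AUC difference by construction
  } else {
    as.numeric(pROC::roc.test(result_a$roc, result_b$roc,
                              method = "delong", paired = TRUE)$p.value)
  }
  tibble(auc_a = result_a$auc, auc_b = result_b$auc,
         auc_diff = result_a$auc - result_b$auc, p_value = p,
         n = length(result_a$labels))
}

#' Modality-by-characteristic ROC report
#'
#' Fits a per-modality PCA on the 38 texture features (each scanner gets its
#' own reduction) and classifies every tumor-characteristic dichotomy from
#' the retained component scores, returning the 2 x 4 grid of AUC,
#' sensitivity, specificity and accuracy. Dichotomies whose preconditions
#' fail on the given cohort (a class absent) yield an `NA` row.
#'
#' @param cohort Cohort feature tibble with label columns.
#' @param dichotomies Named list of [dichotomy()] objects.
#' @param classifier,cv Passed to [score_and_classify()].
#' @return A list with `table` (the report tibble) and `results` (nested
#'   list modality -> dichotomy of `roc_result`, for curve overlays and
#'   [compare_roc()]).
#' @export
table3_report <- function(cohort, dichotomies = default_dichotomies(),
                          classifier = "logistic", cv = FALSE) {
  modalities <- unique(cohort$modality)
  results <- lapply(modalities, function(mod) {
    rows <- cohort[cohort$modality == mod, ]
    model <- fit_pca(rows)
    res <- lapply(dichotomies, function(d) {
      tryCatch(score_and_classify(model, rows, d, classifier = classifier,
                                  cv = cv),
               error = function(e) NULL)
    })
    list(model = model, rocs = res)
  })
  names(results) <- modalities
  tab <- purrr::map_dfr(modalities, function(mod) {
    purrr::map_dfr(dichotomies, function(d) {
      r <- results[[mod]]$rocs[[d$name]]
      if (is.null(r)) {
        tibble(modality = mod, characteristic = d$characteristic,
               contrast = d$contrast, auc = NA_real_, sensitivity = NA_real_,
               specificity = NA_real_, accuracy = NA_real_, n = NA_integer_)
      } else {
        dplyr::bind_cols(
          tibble(modality = mod, characteristic = d$characteristic,
                 contrast = d$contrast),
          glance(r))
      }
    })
  })
  list(table = tab, results = results)
}
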