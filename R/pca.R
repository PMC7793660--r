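# PCA feature reduction with the Kaiser eigenvalue > 1 retention rule.

#' Fit a correlation-matrix PCA on the texture features
#'
#' Features are standardized to zero mean and unit variance (correlation
#' PCA), which is what makes the Kaiser eigenvalue > 1 retention rule
#' meaningful across features of wildly different scales: each standardized
#' feature contributes variance 1, so a retained component explains more than
#' any single feature. The eigenvalues therefore sum to the number of
#' features, and the retained set is every component with eigenvalue > 1.
#'
#' @param cohort Cohort feature tibble (one modality at a time is the usual
#'   workflow, mirroring a per-scanner reduction).
#' @param features Feature columns to reduce (default: the 38 texture
#'   features).
#' @return A `pet_pca`: standardization parameters, loadings, eigenvalues,
#'   `n_retained`, `explained_fraction`.
#' @examples
#' x <- tibble::tibble(a = rnorm(20), b = rnorm(20))
#' fit <- fit_pca(x, features = c("a", "b"))
#' glance(fit)
#' @export
fit_pca <- function(cohort, features = texture_feature_names()) {
  missing <- setdiff(features, names(cohort))
  if (length(missing) > 0) {
    stop_pettex("missing feature columns: %s", paste(missing, collapse = ", "))
  }
  X <- as.matrix(cohort[, features])
  if (nrow(X) < 2) stop_pettex("PCA needs at least 2 lesions")
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    stop_pettex("zero-variance feature(s): %s — drop them explicitly upstream",
                paste(features[sds == 0], collapse = ", "))
  }
  fit <- prcomp(X, center = TRUE, scale. = TRUE)
  ev <- fit$sdev^2
  n_retained <- sum(ev > 1)
  structure(
    list(features = features, center = fit$center, scale = fit$scale,
         loadings = fit$rotation, eigenvalues = ev,
         n_retained = n_retained,
         explained_fraction = sum(ev[ev > 1]) / sum(ev),
         n_obs = nrow(X)),
    class = "pet_pca"
  )
}

#' Project feature rows onto retained principal components
#'
#' @param model A `pet_pca`.
#' @param cohort Cohort feature tibble.
#' @param n_components Number of leading components (default: the retained
#'   set).
#' @return Numeric score matrix (rows x components).
#' @export
pca_scores <- function(model, cohort, n_components = model$n_retained) {
  stopifnot(inherits(model, "pet_pca"))
  X <- as.matrix(cohort[, model$features])
  Z <- scale(X, center = model$center, scale = model$scale)
  Z %*% model$loadings[, seq_len(n_components), drop = FALSE]
}

#' @export
print.pet_pca <- function(x, ...) {
  cat(sprintf(
    "<pet_pca> %d features, %d observations: %d PCs retained (eigenvalue > 1), %.1f%% of variance\n",
    length(x$features), x$n_obs, x$n_retained, 100 * x$explained_fraction))
  invisible(x)
}

#' Tidy a fitted PCA
#'
#' `tidy()` returns the loadings in long form; `glance()` a one-row summary
#' with the retained-component count and explained variance fraction.
#'
#' @param x A `pet_pca`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy pet_pca
#' @export
tidy.pet_pca <- function(x, ...) {
  L <- x$loadings
  tibble(feature = rep(rownames(L), ncol(L)),
         component = rep(seq_len(ncol(L)), each = nrow(L)),
         loading = as.vector(L),
         eigenvalue = rep(x$eigenvalues, each = nrow(L)))
}

#' @rdname tidy.pet_pca
#' @method glance pet_pca
#' @export
glance.pet_pca <- function(x, ...) {
  tibble(n_features = length(x$features), n_obs = x$n_obs,
         n_retained = x$n_retained,
         explained_fraction = x$explained_fraction,
         eigenvalue_sum = sum(x$eigenvalues))
}

#' Scree plot of a fitted PCA
#'
#' @param object A `pet_pca`.
#' @param ... Unused.
#' @return A ggplot object with the Kaiser threshold marked.
#' @method autoplot pet_pca
#' @export
autoplot.pet_pca <- function(object, ...) {
  df <- tibble(component = seq_along(object$eigenvalues),
               eigenvalue = object$eigenvalues)
  ggplot2::ggplot(df, ggplot2::aes(.data$component, .data$eigenvalue)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = "Principal component", y = "Eigenvalue") +
    ggplot2::theme_minimal()
}
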