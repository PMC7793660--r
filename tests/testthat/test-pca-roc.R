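test_that("correlation PCA satisfies the trace identity and the Kaiser rule", {
  co <- noise_cohort(n = 60, seed = 10)
  fit <- fit_pca(co)
  expect_lt(abs(sum(fit$eigenvalues) - 38) / 38, 1e-8)
  expect_equal(fit$n_retained, sum(fit$eigenvalues > 1))
  expect_true(all(diff(fit$eigenvalues) <= 1e-12))
  g <- glance(fit)
  expect_equal(g$n_retained, fit$n_retained)
})

test_that("perfectly collinear features collapse onto one retained component", {
  set.seed(12)
  z <- rnorm(50)
  X <- sapply(1:38, function(j) j * z + j)
  colnames(X) <- texture_feature_names()
  fit <- fit_pca(tibble::as_tibble(X))
  expect_equal(fit$eigenvalues[1], 38, tolerance = 1e-8)
  expect_equal(fit$n_retained, 1L)
  expect_equal(fit$explained_fraction, 1, tolerance = 1e-8)
})

test_that("independent unit-noise features spread eigenvalues around 1", {
  co <- noise_cohort(n = 8000, seed = 14)
  fit <- fit_pca(co)
  expect_lt(max(abs(fit$eigenvalues - 1)), 0.2)
  expect_lt(abs(fit$explained_fraction - fit$n_retained / 38), 0.05)
})

test_that("zero-variance features are refused by name", {
  co <- noise_cohort(n = 20, seed = 15)
  co$RP <- 1
  expect_error(fit_pca(co), "zero-variance feature.*RP")
})

test_that("back-projection with all components reconstructs the standardized data", {
  co <- noise_cohort(n = 45, seed = 16)
  fit <- fit_pca(co)
  X <- as.matrix(co[, fit$features])
  Z <- scale(X, center = fit$center, scale = fit$scale)
  S <- pca_scores(fit, co, n_components = ncol(fit$loadings))
  expect_lt(max(abs(S %*% t(fit$loadings) - Z)), 1e-8)
})

test_that("AUC equals the pairwise concordance oracle", {
  r <- pettex:::roc_from_scores(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))
  expect_equal(r$auc, 0.75)  # 3 of 4 discordance-free pairs
  # constant scores are uninformative
  expect_equal(pettex:::roc_from_scores(c(0, 1, 0, 1), rep(1, 4))$auc, 0.5)
  set.seed(18)
  for (i in 1:25) {
    y <- sample(0:1, 30, replace = TRUE)
    if (length(unique(y)) < 2) next
    s <- sample(round(rnorm(30), 1))  # coarse scores force ties
    expect_equal(pettex:::roc_from_scores(y, s)$auc, oracle_auc(y, s))
  }
})

test_that("no threshold beats the reported Youden operating point", {
  set.seed(19)
  y <- sample(0:1, 40, replace = TRUE)
  s <- round(rnorm(40, mean = y), 1)
  r <- pettex:::roc_from_scores(y, s)
  j_all <- vapply(r$curve$threshold[is.finite(r$curve$threshold)], function(t) {
    mean(s[y == 1] > t) + mean(s[y == 0] <= t) - 1
  }, numeric(1))
  expect_gte(r$sensitivity + r$specificity - 1, max(j_all) - 1e-9)
  acc <- (sum(s[y == 1] > r$threshold) + sum(s[y == 0] <= r$threshold)) / 40
  expect_equal(r$accuracy, acc)
})

test_that("classification on PC scores recovers a strong single-feature effect", {
  set.seed(20)
  co <- noise_cohort(n = 80, seed = 20)
  co$T_category <- rep(c("T1", "T2"), 40)
  co$SDhist <- co$SDhist + 4 * (co$T_category == "T2")
  fit <- fit_pca(co)
  r <- score_and_classify(fit, co, default_dichotomies()$T_category)
  expect_gt(r$auc, 0.95)
  g <- glance(r)
  expect_named(g, c("auc", "sensitivity", "specificity", "accuracy",
                    "threshold", "n"))
  # leave-one-out mode is available and returns a sane AUC
  r_cv <- score_and_classify(fit, co, default_dichotomies()$T_category,
                             cv = TRUE)
  expect_true(r_cv$auc > 0.8 && r_cv$auc <= 1)
  # LDA route
  r_lda <- score_and_classify(fit, co, default_dichotomies()$T_category,
                              classifier = "lda")
  expect_gt(r_lda$auc, 0.9)
})

test_that("a missing class is an error", {
  co <- noise_cohort(n = 20, seed = 21)
  co$T_category <- "T2"
  fit <- fit_pca(co)
  expect_error(score_and_classify(fit, co, default_dichotomies()$T_category),
               "both classes")
})

test_that("paired DeLong comparison behaves at the boundaries", {
  co <- noise_cohort(n = 40, seed = 22)
  fit <- fit_pca(co)
  d <- default_dichotomies()$T_category
  r1 <- score_and_classify(fit, co, d)
  cmp <- compare_roc(r1, r1)
  expect_equal(cmp$auc_diff, 0)
  expect_equal(cmp$p_value, 1)
  # mismatched lesion sets are refused
  co2 <- co
  co2$lesion_id <- paste0("X", co2$lesion_id)
  r2 <- score_and_classify(fit_pca(co2), co2, d)
  expect_error(compare_roc(r1, r2), "different lesion sets")
})

test_that("the paired DeLong test is calibrated and has power", {
  set.seed(24)
  null_rej <- vapply(1:200, function(i) {
    y <- rep(0:1, each = 30)
    ra <- pettex:::roc_from_scores(y, rnorm(60), lesion_id = sprintf("L%02d", 1:60))
    rb <- pettex:::roc_from_scores(y, rnorm(60), lesion_id = sprintf("L%02d", 1:60))
    compare_roc(ra, rb)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(null_rej), 0.01)
  expect_lte(mean(null_rej), 0.10)
  power_rej <- vapply(1:50, function(i) {
    y <- rep(0:1, each = 50)
    ra <- pettex:::roc_from_scores(y, rnorm(100) + 2.4 * y)
    rb <- pettex:::roc_from_scores(y, rnorm(100))
    compare_roc(ra, rb)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(power_rej), 0.9)
})

test_that("the modality-by-characteristic report uses the standard labels", {
  co <- noise_cohort(n = 30, modalities = c("dbPET", "wbPET"), seed = 25)
  rep3 <- table3_report(co)
  expect_equal(nrow(rep3$table), 8)
  expect_setequal(unique(rep3$table$characteristic),
                  c("T-category", "N-category", "Molecular subtype",
                    "Ki67 level"))
  expect_setequal(unique(rep3$table$modality), c("dbPET", "wbPET"))
  expect_true(all(rep3$table$auc >= 0 & rep3$table$auc <= 1, na.rm = TRUE))
  # per-modality PCA fits are separate
  expect_false(identical(rep3$results$dbPET$model$loadings,
                         rep3$results$wbPET$model$loadings))
  # alternative T boundary is supported
  t1 <- default_dichotomies(t_split = "t1")$T_category
  expect_false("Tis" %in% c(t1$group0, t1$group1))
})
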