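test_that("quantization follows the fixed-bin-number formula", {
  vals <- array(0.1, c(6, 6, 6))
  vals[2:5, 3, 3] <- c(1, 2, 3, 4)
  vol <- suv_volume(vals, c(1, 1, 1))
  mask <- array(FALSE, dim(vals))
  mask[2:5, 3, 3] <- TRUE
  voi <- structure(list(mask = mask, suvmax = 4, threshold = 1.6,
                        status = "extracted", n_voxels = 4L,
                        lesion_id = "q", modality = "dbPET"),
                   class = "lesion_voi")
  q <- quantize(vol, voi, G = 4)
  expect_equal(sort(q$levels[!is.na(q$levels)]), 1:4)
  expect_equal(q$suv_min, 1)
  expect_equal(q$suv_max, 4)
})

test_that("quantization endpoints and the degenerate range are handled", {
  set.seed(3)
  fx <- extracted_cube()
  vals <- fx$volume$values
  vals[fx$voi$mask] <- runif(sum(fx$voi$mask), 2, 9)
  vol <- suv_volume(vals, fx$volume$spacing_mm)
  q <- quantize(vol, fx$voi, G = 64)
  lv <- q$levels[!is.na(q$levels)]
  expect_equal(min(lv), 1L)
  expect_equal(max(lv), 64L)
  expect_equal(lv[which.min(q$raw_suv)], 1L)
  expect_equal(lv[which.max(q$raw_suv)], 64L)
  expect_equal(sum(!is.na(q$levels)), fx$voi$n_voxels)
  # uniform lesion: everything collapses to level 1
  qq <- quantize(fx$volume, fx$voi, G = 64)
  expect_true(all(qq$levels[!is.na(qq$levels)] == 1L))
})

test_that("conventional metrics follow their defining arithmetic", {
  vals <- array(0.1, c(10, 10, 4))
  vals[1:10, 1:10, 2] <- 5  # 100-voxel slab
  vol <- suv_volume(vals, c(0.78, 0.78, 2.34))
  voi <- structure(list(mask = vals == 5, suvmax = 5, threshold = 2,
                        status = "extracted", n_voxels = 100L,
                        lesion_id = "m", modality = "dbPET"),
                   class = "lesion_voi")
  m <- conventional_metrics(vol, voi)
  expect_equal(m$MTV, 0.1423656)  # 100 voxels x 1.423656 mm^3 in mL
  expect_equal(m$SUVmean, 5)
  expect_equal(m$TLG, 5 * m$MTV)
  expect_equal(m$NumVoxels, 100L)
  # algebraic identity on an irregular lesion
  set.seed(8)
  fx <- extracted_cube()
  vals2 <- fx$volume$values
  vals2[fx$voi$mask] <- runif(sum(fx$voi$mask), 4, 12)
  m2 <- conventional_metrics(suv_volume(vals2, fx$volume$spacing_mm), fx$voi)
  expect_lt(abs(m2$SUVmean * m2$NumVoxels - m2$SUVsum) / m2$SUVsum, 1e-9)
})

test_that("histogram features match closed forms", {
  # uniform lesion: single occupied bin
  q1 <- line_quantized(rep(1, 9), G = 64)
  h1 <- histogram_features(q1)
  expect_equal(h1$Energy_Hist, 1)
  expect_equal(h1$Entropy_Hist, 0)
  expect_equal(h1$SDhist, 0)
  expect_equal(h1$Skewness, 0)
  expect_equal(h1$Kurtosis, 3)
  # two equiprobable levels: energy 1/2, entropy 1 bit
  q2 <- line_quantized(c(1, 1, 2, 2), G = 2)
  h2 <- histogram_features(q2)
  expect_equal(h2$Energy_Hist, 0.5)
  expect_equal(h2$Entropy_Hist, 1)
  # entropy never exceeds log2(G)
  set.seed(5)
  q3 <- random_quantized(c(6, 6, 6), G = 64, p_mask = 0.9)
  expect_lte(histogram_features(q3)$Entropy_Hist, 6)
  expect_error(histogram_features(line_quantized(1)), ">= 2 voxels")
})

test_that("GLCM features match the exhaustive pair enumeration on a strip", {
  q <- line_quantized(c(1, 1, 2, 2), G = 2)
  M <- glcm_matrix(q, x_dir)
  expect_equal(M, matrix(c(2, 1, 1, 2), 2, 2))
  f <- glcm_features(q, x_dir)
  expect_equal(f$Contrast_GLCM, 2 / 6)
  expect_equal(f$Dissimilarity_GLCM, 2 / 6)
  expect_equal(f$Homogeneity_GLCM, (4 + 2 * 0.5) / 6)
})

test_that("a uniform lesion yields the degenerate GLCM closed forms", {
  q <- as_quantized(array(1L, c(3, 3, 3)), G = 64)
  f <- glcm_features(q)
  expect_equal(f$Homogeneity_GLCM, 1)
  expect_equal(f$Contrast_GLCM, 0)
  expect_equal(f$Energy_GLCM, 1)
  expect_equal(f$Entropy_GLCM, 0)
  expect_equal(f$Correlation_GLCM, 1)  # zero marginal variance convention
})

test_that("a checkerboard is perfectly anti-correlated along axis directions", {
  idx <- expand.grid(1:6, 1:6, 1:1)
  lv <- array(1L + (rowSums(idx) %% 2L), c(6, 6, 1))
  q <- as_quantized(lv, G = 2)
  dirs <- matrix(c(1, 0, 0, 0, 1, 0), 2, 3, byrow = TRUE)
  f <- glcm_features(q, dirs)
  expect_equal(f$Correlation_GLCM, -1)
  from_oracle <- pettex:::glcm_features_from_matrix(oracle_glcm(lv, dirs, 2))
  expect_equal(f, from_oracle)
})

test_that("GLRLM features match run closed forms", {
  # strip [1,1,2,2], single direction: two runs of length 2
  f <- glrlm_features(line_quantized(c(1, 1, 2, 2), G = 2), x_dir)
  expect_equal(f$SRE, 0.25)
  expect_equal(f$RP, 0.5)
  expect_equal(f$GLNUr, 1)
  # uniform line of n: one run, LRE = n^2, RP = 1/n
  n <- 7
  fu <- glrlm_features(line_quantized(rep(1, n)), x_dir)
  expect_equal(fu$LRE, n^2)
  expect_equal(fu$RP, 1 / n)
  # strictly alternating: all runs length 1
  fa <- glrlm_features(line_quantized(rep(c(1, 2), 5), G = 2), x_dir)
  expect_equal(fa$SRE, 1)
  expect_equal(fa$RP, 1)
})

test_that("GLZSM features match zone closed forms", {
  # uniform lesion: a single zone of size n
  n <- 27
  fu <- glzsm_features(as_quantized(array(1L, c(3, 3, 3)), G = 2))
  expect_equal(fu$ZP, 1 / n)
  expect_equal(fu$LZE, n^2)
  # two disjoint blobs of sizes 3 and 5
  lv <- array(NA_integer_, c(11, 1, 1))
  lv[1:3, 1, 1] <- 1L
  lv[7:11, 1, 1] <- 1L
  expect_equal(glzsm_features(as_quantized(lv, G = 2))$GLNUz, 2)  # same level
  lv[7:11, 1, 1] <- 2L
  expect_equal(glzsm_features(as_quantized(lv, G = 2))$GLNUz, 1)  # split levels
  # all-distinct levels: every zone is a singleton
  lv3 <- array(1:8, c(2, 2, 2))
  f3 <- glzsm_features(as_quantized(lv3, G = 8))
  expect_equal(f3$SZE, 1)
  expect_equal(f3$ZP, 1)
})

test_that("NGLDM features follow the Amadasun-King conventions", {
  # uniform: zero differences, capped coarseness
  fu <- ngldm_features(as_quantized(array(1L, c(3, 3, 3)), G = 2))
  expect_equal(fu$Coarseness_NGLDM, 1e9)
  expect_equal(fu$Contrast_NGLDM, 0)
  expect_equal(fu$Busyness_NGLDM, 0)
  # 3-voxel strip [1,2,1]: every voxel differs from its neighborhood mean by 1
  m <- ngldm_matrix(line_quantized(c(1, 2, 1), G = 2))
  expect_equal(m$s, c(2, 1))
  expect_equal(m$n, c(2L, 1L))
  expect_error(ngldm_features(as_quantized(array(1L, c(1, 1, 1)), G = 2)),
               "neighbor")
})

test_that("texture features are invariant to intensity shift and scale", {
  set.seed(13)
  fx <- extracted_cube()
  vals <- fx$volume$values
  vals[fx$voi$mask] <- runif(sum(fx$voi$mask), 3, 11)
  vol <- suv_volume(vals, fx$volume$spacing_mm)
  families <- function(v) {
    q <- quantize(v, fx$voi, G = 16)
    c(histogram_features(q)[c("Energy_Hist", "Entropy_Hist")],
      glcm_features(q), glrlm_features(q), glzsm_features(q),
      ngldm_features(q))
  }
  base <- families(vol)
  shifted <- families(suv_volume(vals + 2.5, vol$spacing_mm))
  scaled <- families(suv_volume(vals * 3.1, vol$spacing_mm))
  expect_equal(shifted, base, tolerance = 1e-12)
  expect_equal(scaled, base, tolerance = 1e-12)
})

test_that("matrices equal their brute-force oracles on random small volumes", {
  set.seed(99)
  dirs <- offsets13()
  for (i in 1:30) {
    q <- random_quantized(c(4, 4, 4), G = sample(3:5, 1))
    lv <- q$levels
    expect_identical(glcm_matrix(q, dirs), oracle_glcm(lv, dirs, q$G))
    expect_identical(glrlm_matrix(q, dirs), oracle_glrlm(lv, dirs, q$G))
    expect_identical(glzsm_matrix(q), oracle_glzsm(lv, q$G))
    o <- oracle_ngldm(lv, q$G)
    m <- ngldm_matrix(q)
    expect_equal(m$s, o$s)
    expect_equal(m$n, o$n)
    expect_equal(m$n_valid, o$n_valid)
  }
})

test_that("merge and average direction aggregation are both available", {
  set.seed(2)
  q <- random_quantized(c(5, 5, 5), G = 4)
  merged <- glcm_features(q, aggregation = "merge")
  averaged <- glcm_features(q, aggregation = "average")
  expect_named(averaged, names(merged))
  expect_false(isTRUE(all.equal(merged$Contrast_GLCM, averaged$Contrast_GLCM)))
  rm <- glrlm_features(q, aggregation = "merge")
  ra <- glrlm_features(q, aggregation = "average")
  expect_named(ra, names(rm))
})

test_that("the feature vector carries exactly the 38 + 4 advertised columns", {
  set.seed(31)
  fx <- extracted_cube()
  vals <- fx$volume$values
  vals[fx$voi$mask] <- runif(sum(fx$voi$mask), 3, 9)
  vol <- suv_volume(vals, fx$volume$spacing_mm, modality = "dbPET",
                    lesion_id = "fix")
  fv <- feature_vector(vol, fx$voi)
  expect_identical(setdiff(names(fv), c("lesion_id", "modality")),
                   c(conventional_metric_names(), texture_feature_names()))
  expect_length(texture_feature_names(), 38)
  expect_true(all(is.finite(unlist(fv[, -(1:2)]))))
  expect_lt(abs(fv$TLG - fv$MTV * fv$SUVmean), 1e-9 * fv$TLG)
  # the degenerate flat lesion also yields a fully finite vector
  fu <- feature_vector(fx$volume, fx$voi)
  expect_true(all(is.finite(unlist(fu[, -(1:2)]))))
  expect_equal(fu$Energy_Hist, 1)
  expect_equal(fu$Homogeneity_GLCM, 1)
})
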