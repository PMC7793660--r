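test_that("a flat hot lesion on a cold background is delineated completely", {
  fx <- cube_lesion(value = 10, bg = 1)
  voi <- extract_lesion(fx$volume, fx$seed, fx$bg)
  expect_equal(voi$status, "extracted")
  expect_equal(voi$suvmax, 10)
  expect_equal(voi$threshold, 4)
  # background (1 < 4) excluded, every lesion voxel (10 >= 4) included
  expect_identical(voi$mask, fx$volume$values == 10)
  expect_true(all(fx$volume$values[voi$mask] >= voi$threshold))
})

test_that("the background rule fails extraction exactly at 40% of SUVmax", {
  make_vol <- function(bg_value) {
    vals <- array(0.5, c(12, 12, 12))
    vals[5:8, 5:8, 5:8] <- 5
    vals[1:3, 1:3, 1:3] <- bg_value
    suv_volume(vals, c(1, 1, 1))
  }
  seed <- seed_sphere(c(5.5, 5.5, 5.5), 5)
  bg <- seed_sphere(c(1, 1, 1), 1.8)
  # mean background 2.5 >= 0.4 * 5: excluded
  voi <- extract_lesion(make_vol(2.5), seed, bg)
  expect_equal(voi$status, "failed_background")
  expect_equal(voi$n_voxels, 0L)
  expect_false(any(voi$mask))
  # boundary: exactly at the threshold still fails (>=, not >)
  expect_equal(extract_lesion(make_vol(2.0), seed, bg)$status,
               "failed_background")
  expect_equal(extract_lesion(make_vol(1.99), seed, bg)$status, "extracted")
})

test_that("only the connected component containing the hottest voxel is kept", {
  vals <- array(0.5, c(15, 15, 15))
  vals[3:5, 7:9, 7:9] <- 10   # hot blob (contains the max)
  vals[11:13, 7:9, 7:9] <- 9  # second blob above threshold, disconnected
  vol <- suv_volume(vals, c(1, 1, 1))
  voi <- extract_lesion(vol, seed_sphere(c(7, 7, 7), 9),
                        seed_sphere(c(0, 0, 0), 1.8))
  expect_identical(voi$mask, vals == 10)
  expect_identical(voi$mask,
                   oracle_flood(vals >= voi$threshold, which(vals == 10)[1]))
})

test_that("masks agree with an independent flood-fill oracle on random volumes", {
  set.seed(42)
  for (i in 1:20) {
    vals <- array(runif(9^3, 0, 5), c(9, 9, 9))
    vals[1:2, 1:2, 1:2] <- 0
    corner <- which(vals == 0)
    hot <- sample(setdiff(seq_len(9^3), corner), 1)
    vals[hot] <- 10
    vol <- suv_volume(vals, c(1, 1, 1))
    seed <- seed_sphere(which(array(seq_along(vals), dim(vals)) == hot,
                              arr.ind = TRUE)[1, ] - 1, runif(1, 3, 5))
    voi <- extract_lesion(vol, seed, seed_sphere(c(0.5, 0.5, 0.5), 1.2))
    in_seed <- pettex:::sphere_mask(vol, seed)
    cand <- in_seed & (vals >= voi$threshold)
    expect_identical(voi$mask, oracle_flood(cand, which(vals == 10)[1]))
  }
})

test_that("raising the relative threshold never grows the mask", {
  set.seed(7)
  vals <- array(runif(11^3, 0, 8), c(11, 11, 11))
  vals[6, 6, 6] <- 12
  vals[1:2, 1:2, 1:2] <- 0
  vol <- suv_volume(vals, c(1, 1, 1))
  seed <- seed_sphere(c(5, 5, 5), 4.5)
  bg <- seed_sphere(c(0.5, 0.5, 0.5), 1.2)
  prev <- NULL
  for (f in c(0.3, 0.4, 0.5, 0.65, 0.8)) {
    m <- extract_lesion(vol, seed, bg, threshold_fraction = f)$mask
    if (!is.null(prev)) expect_true(all(prev | !m))  # m subset of prev
    prev <- m
  }
})

test_that("the relative threshold makes the mask scale invariant", {
  set.seed(11)
  vals <- array(runif(10^3, 0.1, 6), c(10, 10, 10))
  vals[5, 5, 5] <- 9
  vals[1:2, 1:2, 1:2] <- 0.01
  vol <- suv_volume(vals, c(1, 1, 1))
  seed <- seed_sphere(c(4, 4, 4), 4)
  bg <- seed_sphere(c(0.5, 0.5, 0.5), 1.2)
  voi1 <- extract_lesion(vol, seed, bg)
  voi2 <- extract_lesion(suv_volume(vals * 3.7, c(1, 1, 1)), seed, bg)
  expect_identical(voi1$mask, voi2$mask)
  expect_equal(voi2$suvmax, 3.7 * voi1$suvmax)
})

test_that("degenerate seed and background regions are rejected", {
  vol <- suv_volume(array(1, c(5, 5, 5)), c(1, 1, 1))
  expect_error(extract_lesion(vol, seed_sphere(c(50, 50, 50), 1),
                              seed_sphere(c(0, 0, 0), 1)), "seed sphere")
  expect_error(extract_lesion(vol, seed_sphere(c(2, 2, 2), 2),
                              seed_sphere(c(50, 50, 50), 1)), "background")
})

test_that("a lesion failing in one modality is excluded from the paired set", {
  voi_stub <- function(id, mod, status, n) {
    structure(list(mask = array(status == "extracted", c(1, 1, 1)),
                   suvmax = 5, threshold = 2, status = status,
                   n_voxels = n, lesion_id = id, modality = mod),
              class = "lesion_voi")
  }
  vois <- list(
    L001 = list(dbPET = voi_stub("L001", "dbPET", "extracted", 40),
                wbPET = voi_stub("L001", "wbPET", "extracted", 5)),
    L002 = list(dbPET = voi_stub("L002", "dbPET", "extracted", 38),
                wbPET = voi_stub("L002", "wbPET", "failed_background", 0))
  )
  rep <- extraction_report(vois)
  expect_equal(nrow(rep), 4)
  expect_false(any(rep$excluded[rep$lesion_id == "L001"]))
  expect_true(all(rep$excluded[rep$lesion_id == "L002"]))
  expect_equal(rep$reason[rep$lesion_id == "L002" & rep$modality == "wbPET"],
               "failed_background")
  # all-extracted cohort: every lesion retained
  vois$L002$wbPET <- voi_stub("L002", "wbPET", "extracted", 4)
  expect_false(any(extraction_report(vois)$excluded))
})

test_that("small faint lesions fail the background rule only on the coarse scanner", {
  db_status <- character(10)
  wb_status <- character(10)
  for (s in 1:10) {
    spec <- phantom_spec(c(2, 2, 2), lesion_mean_suv = 6, background_suv = 1.5,
                         heterogeneity_amplitude = 0.2, fov_mm = c(24, 24, 24),
                         seed = s)
    truth <- render_ground_truth(spec)
    seed <- seed_sphere(spec$lesion_center_mm, 6)
    bg <- seed_sphere(c(3, 3, 3), 5)
    db <- image_with_modality(truth, dbpet_profile(), 0.05, seed = s + 100)
    wb <- image_with_modality(truth, wbpet_profile(), 0.05, seed = s + 200)
    db_status[s] <- extract_lesion(db, seed, bg)$status
    wb_status[s] <- extract_lesion(wb, seed, bg)$status
  }
  # at least one replicate is extractable on dbPET but lost on wbPET
  expect_gte(sum(db_status == "extracted" & wb_status == "failed_background"), 1)
  # and the coarse scanner never succeeds where the fine one fails
  expect_false(any(db_status == "failed_background" & wb_status == "extracted"))
})
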