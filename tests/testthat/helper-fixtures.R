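# Small in-code fixtures shared across test files.

# A cube lesion of constant SUV on a low background, with a generous seed
# sphere and a quiet background corner.
cube_lesion <- function(value = 10, bg = 0.5, n = 12, spacing = c(1, 1, 1),
                        lo = 5, hi = 8) {
  vals <- array(bg, c(n, n, n))
  vals[lo:hi, lo:hi, lo:hi] <- value
  vol <- suv_volume(vals, spacing, modality = "dbPET", lesion_id = "fix")
  center <- (c(lo, lo, lo) + c(hi, hi, hi)) / 2 - 1
  list(volume = vol,
       seed = seed_sphere(center * spacing, (hi - lo + 2) * max(spacing)),
       bg = seed_sphere(c(0, 0, 0), 1.6 * max(spacing)))
}

extracted_cube <- function(...) {
  fx <- cube_lesion(...)
  fx$voi <- extract_lesion(fx$volume, fx$seed, fx$bg)
  fx
}

# A single-direction line fixture as a quantized lesion.
line_quantized <- function(levels, G = max(levels)) {
  lv <- array(NA_integer_, c(length(levels), 1, 1))
  lv[, 1, 1] <- as.integer(levels)
  as_quantized(lv, G = G)
}

x_dir <- matrix(c(1L, 0L, 0L), nrow = 1)

# Minimal feature cohort for statistics / PCA tests: `n` lesions per
# modality with all 38 texture columns of iid noise (plus labels).
noise_cohort <- function(n = 40, modalities = "dbPET", seed = 1) {
  withr::with_seed(seed, {
    purrr::map_dfr(modalities, function(mod) {
      X <- matrix(rnorm(n * 38), n, 38)
      colnames(X) <- texture_feature_names()
      df <- tibble::as_tibble(X)
      df$lesion_id <- sprintf("L%03d", seq_len(n))
      df$modality <- mod
      df$T_category <- sample(c("T1", "T2"), n, replace = TRUE)
      df$N_category <- sample(c("N0", "N1"), n, replace = TRUE)
      df$subtype <- sample(c("Luminal A", "HER2"), n, replace = TRUE)
      df$ki67 <- sample(c("<20%", ">=20%"), n, replace = TRUE)
      df
    })
  })
}
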