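#' Modality acquisition profiles
#'
#' A modality profile describes how a scanner renders a ground-truth activity
#' map: its reconstructed voxel grid and the FWHM of its post-reconstruction
#' Gaussian smoothing. The two built-in profiles correspond to a
#' high-resolution ring-shaped dedicated breast PET (dbPET: 0.78 x 0.78 x
#' 2.34 mm voxels, 1.17 mm FWHM) and a whole-body PET/CT (wbPET: 4.11 x 4.11 x
#' 5 mm voxels, 5 mm FWHM).
#'
#' @param name Modality label.
#' @param voxel_spacing_mm Positive 3-vector of reconstructed voxel spacing.
#' @param psf_fwhm_mm Positive scalar, FWHM of the post-reconstruction
#'   Gaussian smoothing in mm.
#' @return A `modality_profile` object.
#' @examples
#' dbpet_profile()
#' wbpet_profile()
#' @export
modality_profile <- function(name, voxel_spacing_mm, psf_fwhm_mm) {
  voxel_spacing_mm <- check_length3(voxel_spacing_mm, "voxel_spacing_mm")
  if (any(voxel_spacing_mm <= 0)) stop_pettex("voxel spacing must be positive")
  if (!is.numeric(psf_fwhm_mm) || length(psf_fwhm_mm) != 1L || psf_fwhm_mm <= 0) {
    stop_pettex("`psf_fwhm_mm` must be a single positive number")
  }
  structure(list(name = name, voxel_spacing_mm = voxel_spacing_mm,
                 psf_fwhm_mm = as.numeric(psf_fwhm_mm)),
            class = "modality_profile")
}

#' @rdname modality_profile
#' @export
dbpet_profile <- function() {
  modality_profile("dbPET", c(0.78, 0.78, 2.34), 1.17)
}

#' @rdname modality_profile
#' @export
wbpet_profile <- function() {
  modality_profile("wbPET", c(4.11, 4.11, 5.0), 5.0)
}

#' @rdname modality_profile
#' @export
default_profiles <- function() {
  list(dbPET = dbpet_profile(), wbPET = wbpet_profile())
}

#' Ground-truth lesion phantom specification
#'
#' Describes one synthetic lesion before any scanner effect: an ellipsoidal
#' region of elevated uptake on a uniform background, with an optional smooth
#' Gaussian random field superposed inside the lesion to emulate intra-tumoral
#' heterogeneity. The heterogeneity field is white noise convolved with a
#' Gaussian kernel of the stated correlation length, standardized to unit SD
#' inside the lesion and scaled by `heterogeneity_amplitude * lesion_mean_suv`.
#'
#' @param lesion_radii_mm Positive 3-vector of ellipsoid semi-axes (mm). The
#'   lesion size is the phantom analogue of the clinical T-category.
#' @param lesion_center_mm Lesion center (mm); defaults to the grid center.
#' @param lesion_mean_suv Mean lesion SUV; must exceed `background_suv`.
#' @param background_suv Background SUV, `>= 0`.
#' @param heterogeneity_amplitude Fraction of `lesion_mean_suv` used as the SD
#'   of the intra-lesion field; in `[0, 1)`.
#' @param heterogeneity_correlation_length_mm Correlation length (Gaussian
#'   kernel sigma, mm) of the intra-lesion field. The default (1.5 mm) places
#'   the texture scale near the dbPET voxel size and well below the wbPET
#'   voxel size, i.e. millimetric heterogeneity.
#' @param noise_sd_suv Default SD (SUV) of the additive measurement noise
#'   applied by [image_with_modality()].
#' @param fov_mm Field of view (mm) of the ground-truth grid, 3-vector.
#' @param seed Integer seed making the phantom a pure function of this spec.
#' @return A `phantom_spec` object.
#' @examples
#' spec <- phantom_spec(lesion_radii_mm = c(8, 8, 8), seed = 1)
#' vol <- render_ground_truth(spec)
#' @export
phantom_spec <- function(lesion_radii_mm,
                         lesion_center_mm = NULL,
                         lesion_mean_suv = 8,
                         background_suv = 0.8,
                         heterogeneity_amplitude = 0.3,
                         heterogeneity_correlation_length_mm = 1.5,
                         noise_sd_suv = 0.05,
                         fov_mm = c(48, 48, 48),
                         seed = 1L) {
  lesion_radii_mm <- check_length3(lesion_radii_mm, "lesion_radii_mm")
  fov_mm <- check_length3(fov_mm, "fov_mm")
  if (is.null(lesion_center_mm)) lesion_center_mm <- fov_mm / 2
  lesion_center_mm <- check_length3(lesion_center_mm, "lesion_center_mm")
  if (any(lesion_radii_mm <= 0) || any(fov_mm <= 0) ||
      heterogeneity_correlation_length_mm <= 0) {
    stop_pettex("all lengths must be positive")
  }
  if (!(lesion_mean_suv > background_suv && background_suv >= 0)) {
    stop_pettex("need lesion_mean_suv > background_suv >= 0")
  }
  if (heterogeneity_amplitude < 0 || heterogeneity_amplitude >= 1) {
    stop_pettex("`heterogeneity_amplitude` must be in [0, 1)")
  }
  if (noise_sd_suv < 0) stop_pettex("`noise_sd_suv` must be nonnegative")
  structure(
    list(lesion_radii_mm = lesion_radii_mm,
         lesion_center_mm = lesion_center_mm,
         lesion_mean_suv = lesion_mean_suv,
         background_suv = background_suv,
         heterogeneity_amplitude = heterogeneity_amplitude,
         heterogeneity_correlation_length_mm = heterogeneity_correlation_length_mm,
         noise_sd_suv = noise_sd_suv,
         fov_mm = fov_mm,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# --- separable Gaussian smoothing -------------------------------------------

# Dense 1D convolution matrix with a truncated Gaussian kernel; rows are
# renormalized so a constant input is preserved exactly at the boundaries.
gauss_conv_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  half <- max(1L, ceiling(4 * sigma_vox))
  i <- seq_len(n)
  K <- outer(i, i, function(a, b) {
    d <- a - b
    ifelse(abs(d) <= half, exp(-d^2 / (2 * sigma_vox^2)), 0)
  })
  K / rowSums(K)
}

apply_axis <- function(arr, axis, M) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  dp <- dim(a)
  out <- M %*% matrix(a, nrow = dp[1])
  dim(out) <- c(nrow(M), dp[2], dp[3])
  aperm(out, order(perm))
}

gauss_smooth3 <- function(arr, sigma_vox) {
  for (ax in 1:3) {
    if (sigma_vox[ax] > 0) {
      arr <- apply_axis(arr, ax, gauss_conv_matrix(dim(arr)[ax], sigma_vox[ax]))
    }
  }
  arr
}

# --- partial-volume rebinning -----------------------------------------------

# 1D overlap-weighted rebinning matrix from a fine grid (spacing f) to a
# coarse grid (spacing c). Voxel-0 centers of the two grids coincide; each
# coarse voxel value is the overlap-weighted mean of the fine voxels it
# covers (weights renormalized, so constants are preserved exactly).
rebin_matrix <- function(n_fine, f, c_) {
  if (abs(c_ - f) < 1e-9) return(diag(n_fine))
  n_coarse <- floor((n_fine - 1) * f / c_ + 1e-9) + 1L
  fine_lo <- (seq_len(n_fine) - 1) * f - f / 2
  fine_hi <- fine_lo + f
  W <- matrix(0, n_coarse, n_fine)
  for (k in seq_len(n_coarse)) {
    lo <- (k - 1) * c_ - c_ / 2
    hi <- lo + c_
    ov <- pmax(0, pmin(hi, fine_hi) - pmax(lo, fine_lo))
    W[k, ] <- ov
  }
  W / rowSums(W)
}

#' Render a ground-truth activity map
#'
#' Produces the noiseless, scanner-free SUV volume of one phantom lesion on a
#' fine isotropic grid (default 0.5 mm): an ellipsoid of mean uptake
#' `lesion_mean_suv` with the spec's smooth heterogeneity field superposed
#' inside the lesion, a uniform background elsewhere, clipped to nonnegative
#' values. Deterministic given `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @param grid_spacing_mm Fine-grid spacing (mm), 3-vector or scalar.
#' @return An [suv_volume()] with modality `"truth"`.
#' @export
render_ground_truth <- function(spec, grid_spacing_mm = c(0.5, 0.5, 0.5)) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (length(grid_spacing_mm) == 1L) grid_spacing_mm <- rep(grid_spacing_mm, 3)
  grid_spacing_mm <- check_length3(grid_spacing_mm, "grid_spacing_mm")
  dims <- pmax(2L, floor(spec$fov_mm / grid_spacing_mm + 1e-9))
  extent <- (dims - 1) * grid_spacing_mm
  lo <- spec$lesion_center_mm - spec$lesion_radii_mm
  hi <- spec$lesion_center_mm + spec$lesion_radii_mm
  bad <- which(lo < 0 | hi > extent)
  if (length(bad) > 0) {
    stop_pettex("lesion extends outside the grid along axis %s",
                paste(axis_names[bad], collapse = ", "))
  }
  d2 <- dist2_array(dims, grid_spacing_mm, spec$lesion_center_mm,
                    scale = spec$lesion_radii_mm)
  lesion <- d2 <= 1
  values <- array(spec$background_suv, dims)
  values[lesion] <- spec$lesion_mean_suv
  if (spec$heterogeneity_amplitude > 0) {
    field <- with_local_seed(spec$seed, array(rnorm(prod(dims)), dims))
    field <- gauss_smooth3(
      field, spec$heterogeneity_correlation_length_mm / grid_spacing_mm)
    s <- sd(field[lesion])
    if (s > 0) {
      field <- field / s * spec$heterogeneity_amplitude * spec$lesion_mean_suv
      values[lesion] <- values[lesion] + field[lesion]
    }
  }
  values[values < 0] <- 0
  suv_volume(values, grid_spacing_mm, modality = "truth")
}

#' Simulate a modality acquisition of a ground-truth volume
#'
#' Applies the modality's point-spread function as a separable Gaussian
#' convolution at the stated FWHM on the fine grid, rebins to the modality
#' voxel grid by overlap-weighted averaging (the partial-volume step), and
#' adds voxelwise Gaussian noise in SUV units, clipping to nonnegative.
#'
#' @param truth An [suv_volume()] on a grid at least as fine as the profile
#'   grid on every axis.
#' @param profile A [modality_profile()].
#' @param noise_sd_suv SD of the additive Gaussian noise (SUV); 0 disables it.
#' @param seed Seed for the noise draw.
#' @return An [suv_volume()] on the modality grid.
#' @export
image_with_modality <- function(truth, profile, noise_sd_suv = 0, seed = NULL) {
  stopifnot(inherits(truth, "suv_volume"), inherits(profile, "modality_profile"))
  if (profile$psf_fwhm_mm <= 0) stop_pettex("PSF FWHM must be positive")
  if (any(truth$spacing_mm > profile$voxel_spacing_mm + 1e-9)) {
    stop_pettex("truth grid must be at least as fine as the %s grid on every axis",
                profile$name)
  }
  sigma_mm <- profile$psf_fwhm_mm / (2 * sqrt(2 * log(2)))
  blurred <- gauss_smooth3(truth$values, sigma_mm / truth$spacing_mm)
  out <- blurred
  for (ax in 1:3) {
    out <- apply_axis(out, ax, rebin_matrix(dim(out)[ax], truth$spacing_mm[ax],
                                            profile$voxel_spacing_mm[ax]))
  }
  if (noise_sd_suv > 0) {
    noise <- with_local_seed(seed, array(rnorm(length(out), sd = noise_sd_suv), dim(out)))
    out <- out + noise
  }
  out[out < 0] <- 0
  suv_volume(out, profile$voxel_spacing_mm, modality = profile$name,
             lesion_id = truth$lesion_id)
}
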