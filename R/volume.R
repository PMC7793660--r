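#' SUV volume container
#'
#' A lightweight container for a 3D standardized-uptake-value (SUV) image: a
#' numeric array plus its anisotropic voxel spacing in mm and optional
#' modality / lesion identifiers. All downstream stages (delineation, texture
#' features) consume this type.
#'
#' Physical coordinates follow a voxel-center convention: the center of the
#' first voxel (R index `[1, 1, 1]`) is at the origin, so R index `i` maps to
#' `(i - 1) * spacing` mm along each axis.
#'
#' @param values Numeric 3D array of SUV values; must be finite and
#'   nonnegative (SUV is a nonnegative, dose- and body-weight-corrected
#'   concentration; volumes flagged as raw counts are refused upstream).
#' @param spacing_mm Numeric 3-vector of voxel spacing in mm, all positive.
#' @param modality Optional modality label (e.g. `"dbPET"`, `"wbPET"`).
#' @param lesion_id Optional lesion identifier.
#'
#' @return An object of class `suv_volume`.
#' @examples
#' vol <- suv_volume(array(1, c(4, 4, 4)), spacing_mm = c(0.78, 0.78, 2.34))
#' vol
#' @export
suv_volume <- function(values, spacing_mm, modality = NA_character_,
                       lesion_id = NA_character_) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop_pettex("`values` must be a 3D array")
  }
  spacing_mm <- check_length3(spacing_mm, "spacing_mm")
  if (any(spacing_mm <= 0)) stop_pettex("voxel spacing must be positive on every axis")
  if (anyNA(values) || any(!is.finite(values))) {
    stop_pettex("SUV values must all be finite")
  }
  n_neg <- sum(values < 0)
  if (n_neg > 0) {
    stop_pettex("SUV values must be nonnegative; %d negative voxel(s) found", n_neg)
  }
  structure(
    list(values = values, spacing_mm = spacing_mm,
         modality = modality, lesion_id = lesion_id),
    class = "suv_volume"
  )
}

#' @export
print.suv_volume <- function(x, ...) {
  cat(sprintf(
    "<suv_volume> %s  %d x %d x %d voxels @ %.3g x %.3g x %.3g mm  SUV [%.3g, %.3g]\n",
    x$modality, dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
    x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3],
    min(x$values), max(x$values)
  ))
  invisible(x)
}

#' @export
dim.suv_volume <- function(x) dim(x$values)

#' Spherical region in physical coordinates
#'
#' A sphere specified in mm in the volume's physical frame, used both as the
#' lesion seed (the spherical VOI within which the lesion is delineated) and
#' as the background reference region. Specifying spheres in mm rather than
#' voxel indices lets the same seed address both modality grids.
#'
#' @param center_mm Numeric 3-vector, sphere center in mm.
#' @param radius_mm Positive sphere radius in mm.
#' @return An object of class `seed_sphere`.
#' @examples
#' seed_sphere(c(12, 12, 12), 8)
#' @export
seed_sphere <- function(center_mm, radius_mm) {
  center_mm <- check_length3(center_mm, "center_mm")
  if (!is.numeric(radius_mm) || length(radius_mm) != 1L || radius_mm <= 0) {
    stop_pettex("`radius_mm` must be a single positive number")
  }
  structure(list(center_mm = center_mm, radius_mm = as.numeric(radius_mm)),
            class = "seed_sphere")
}

# Logical array: voxel centers inside the sphere.
sphere_mask <- function(volume, sphere) {
  d2 <- dist2_array(dim(volume$values), volume$spacing_mm, sphere$center_mm)
  d2 <= sphere$radius_mm^2
}

#' Read an SUV volume from a NIfTI file
#'
#' Voxel spacing is taken from the NIfTI header (`pixdim`); a header with
#' non-positive spacing is rejected rather than silently assumed isotropic.
#' Axis order follows the on-disk array order, interpreted as (x, y, z) with
#' the voxel-center-at-origin convention of [suv_volume()].
#'
#' @param path Path to a NIfTI file.
#' @param modality,lesion_id Optional labels attached to the volume.
#' @return An [suv_volume()].
#' @export
read_volume <- function(path, modality = NA_character_, lesion_id = NA_character_) {
  if (!file.exists(path)) stop_pettex("file not found: %s", path)
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3]
  if (anyNA(spacing) || any(spacing <= 0)) {
    stop_pettex("volume %s has missing or non-positive voxel spacing in its header", path)
  }
  values <- array(as.numeric(img), dim = dim(img)[1:3])
  suv_volume(values, spacing, modality = modality, lesion_id = lesion_id)
}

#' Write an SUV volume to a NIfTI file
#'
#' @param volume An [suv_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "suv_volume"))
  img <- RNifti::asNifti(volume$values)
  RNifti::pixdim(img) <- volume$spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write or read lesion seed spheres as a JSON sidecar
#'
#' Seed spheres are stored per lesion in physical (mm) coordinates so that a
#' single sidecar addresses every modality grid of the same lesion.
#'
#' @param seeds A named list of [seed_sphere()] objects (names = lesion ids),
#'   or a tibble with columns `lesion_id`, `cx`, `cy`, `cz`, `radius_mm`.
#' @param path JSON file path.
#' @return `read_seed_spheres()` returns a named list of [seed_sphere()].
#' @export
write_seed_spheres <- function(seeds, path) {
  if (is.data.frame(seeds)) {
    seeds <- setNames(
      lapply(seq_len(nrow(seeds)), function(i) {
        seed_sphere(c(seeds$cx[i], seeds$cy[i], seeds$cz[i]), seeds$radius_mm[i])
      }),
      seeds$lesion_id
    )
  }
  payload <- lapply(seeds, function(s) {
    list(center_mm = s$center_mm, radius_mm = s$radius_mm)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_seed_spheres
#' @export
read_seed_spheres <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(payload, function(s) seed_sphere(unlist(s$center_mm), s$radius_mm))
}
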