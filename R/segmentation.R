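# Lesion delineation: relative threshold at 40% of SUVmax inside a spherical
# seed VOI, restricted to the 26-connected component containing the hottest
# voxel, with the background-extractability exclusion rule.

# The 13 unique 3D neighbor offsets at Chebyshev distance 1 (the other 13 are
# their negatives). First nonzero component is +1 by construction.
offsets13 <- function() {
  m <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  m <- m[!(m[, 1] == 0 & m[, 2] == 0 & m[, 3] == 0), , drop = FALSE]
  keep <- apply(m, 1, function(o) {
    nz <- o[o != 0]
    nz[1] > 0
  })
  unname(m[keep, , drop = FALSE])
}

# Edge list (pairs of row indices of `coords`) of the 26-adjacency graph over
# an arbitrary voxel subset. `coords` is an n x 3 integer matrix.
adjacency_pairs_26 <- function(coords) {
  n <- nrow(coords)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  off <- apply(coords, 2, min) - 2L
  dims <- apply(coords, 2, max) - off + 2L
  key <- (coords[, 1] - off[1]) +
    (coords[, 2] - off[2]) * dims[1] +
    (coords[, 3] - off[3]) * dims[1] * dims[2]
  pairs <- list()
  offs <- offsets13()
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    nb_key <- key + o[1] + o[2] * dims[1] + o[3] * dims[1] * dims[2]
    j <- match(nb_key, key)
    ok <- !is.na(j)
    if (any(ok)) pairs[[length(pairs) + 1L]] <- cbind(which(ok), j[ok])
  }
  if (length(pairs) == 0) return(matrix(integer(0), ncol = 2))
  do.call(rbind, pairs)
}

# Component membership (integer vector) of the 26-adjacency graph over coords.
components_26 <- function(coords) {
  n <- nrow(coords)
  if (n == 0) return(integer(0))
  pairs <- adjacency_pairs_26(coords)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(pairs) > 0) g <- igraph::add_edges(g, t(pairs))
  igraph::components(g)$membership
}

#' Delineate a lesion by the 40%-of-SUVmax relative threshold
#'
#' SUVmax is the maximum SUV over voxel centers inside the seed sphere. The
#' lesion mask is the 26-connected component of voxels at or above
#' `threshold_fraction * SUVmax` that contains the hottest voxel, clipped to
#' the seed sphere. If the mean SUV over the background region reaches the
#' threshold, extraction fails (`failed_background`) and the mask is empty —
#' the exclusion rule applied when the background mammary gland uptake exceeds
#' 40% of the lesion SUVmax.
#'
#' Ties: voxels exactly at the threshold are included; if several voxels
#' attain SUVmax, the first in lexicographic index order anchors the
#' component.
#'
#' @param volume An [suv_volume()].
#' @param seed A [seed_sphere()] containing at least one voxel center.
#' @param background_region A [seed_sphere()] over background tissue.
#' @param threshold_fraction Relative threshold (default 0.40).
#' @return A `lesion_voi`: logical `mask` aligned to the volume, `suvmax`,
#'   `threshold`, `status` (`"extracted"` or `"failed_background"`),
#'   `n_voxels`, plus the input identifiers.
#' @examples
#' vol <- suv_volume(array(1, c(9, 9, 9)), c(1, 1, 1))
#' vol$values[4:6, 4:6, 4:6] <- 10
#' voi <- extract_lesion(vol, seed_sphere(c(4, 4, 4), 4),
#'                       seed_sphere(c(1, 1, 1), 1.2))
#' voi$status
#' @export
extract_lesion <- function(volume, seed, background_region,
                           threshold_fraction = 0.40) {
  stopifnot(inherits(volume, "suv_volume"), inherits(seed, "seed_sphere"),
            inherits(background_region, "seed_sphere"))
  if (threshold_fraction <= 0 || threshold_fraction >= 1) {
    stop_pettex("`threshold_fraction` must lie in (0, 1)")
  }
  in_seed <- sphere_mask(volume, seed)
  if (!any(in_seed)) stop_pettex("seed sphere contains no voxel centers")
  in_bg <- sphere_mask(volume, background_region)
  if (!any(in_bg)) stop_pettex("background region contains no voxel centers")

  vals <- volume$values
  suvmax <- max(vals[in_seed])
  threshold <- threshold_fraction * suvmax
  bg_mean <- mean(vals[in_bg])

  mask <- array(FALSE, dim(vals))
  status <- "extracted"
  if (bg_mean >= threshold) {
    status <- "failed_background"
  } else {
    cand <- in_seed & (vals >= threshold)
    coords <- which(cand, arr.ind = TRUE)
    # first lexicographic max voxel within the seed sphere
    seed_idx <- which(in_seed & vals == suvmax)[1]
    cand_idx <- which(cand)
    memb <- components_26(coords)
    keep <- memb == memb[match(seed_idx, cand_idx)]
    mask[cand_idx[keep]] <- TRUE
  }
  structure(
    list(mask = mask, suvmax = suvmax, threshold = threshold,
         threshold_fraction = threshold_fraction, status = status,
         background_mean = bg_mean, n_voxels = sum(mask),
         lesion_id = volume$lesion_id, modality = volume$modality),
    class = "lesion_voi"
  )
}

#' @export
print.lesion_voi <- function(x, ...) {
  cat(sprintf("<lesion_voi> %s/%s  status=%s  SUVmax=%.3g  threshold=%.3g  voxels=%d\n",
              x$lesion_id, x$modality, x$status, x$suvmax, x$threshold, x$n_voxels))
  invisible(x)
}

#' Delineate every lesion of a cohort in every modality
#'
#' Builds a per-lesion seed sphere from the phantom geometry (the lesion
#' center and its largest semi-axis, padded for scanner blur) and a fixed
#' background sphere near a grid corner, then runs [extract_lesion()] on each
#' modality volume.
#'
#' @param cohort A `pet_cohort` from [generate_cohort()].
#' @param seed_radius_factor,seed_pad_mm Seed radius =
#'   `factor * max(semi-axes) + pad`.
#' @param background_frac Background sphere center as a fraction of the field
#'   of view on each axis.
#' @param background_radius_mm Background sphere radius (>= 4 mm guarantees a
#'   voxel center on the coarse wbPET grid).
#' @param threshold_fraction Relative threshold, see [extract_lesion()].
#' @return A `pet_extraction`: `vois` (nested list lesion -> modality),
#'   `report` (tibble from [extraction_report()]), and the input `cohort`.
#' @export
extract_cohort <- function(cohort, seed_radius_factor = 1.3, seed_pad_mm = 4,
                           background_frac = 0.12, background_radius_mm = 5,
                           threshold_fraction = 0.40) {
  stopifnot(inherits(cohort, "pet_cohort"))
  vois <- lapply(cohort$lesions, function(les) {
    seed <- seed_sphere(
      les$spec$lesion_center_mm,
      seed_radius_factor * max(les$spec$lesion_radii_mm) + seed_pad_mm)
    bg <- seed_sphere(background_frac * les$spec$fov_mm, background_radius_mm)
    lapply(les$volumes, extract_lesion, seed = seed, background_region = bg,
           threshold_fraction = threshold_fraction)
  })
  structure(list(cohort = cohort, vois = vois,
                 report = extraction_report(vois)),
            class = "pet_extraction")
}

#' Per-lesion, per-modality extraction report
#'
#' Records the extraction status of every lesion in every modality and flags
#' for exclusion any lesion that failed in at least one modality, mirroring a
#' paired design where a lesion must be extractable on both scanners to enter
#' the analysis.
#'
#' @param vois A nested list (lesion -> modality) of `lesion_voi` objects, or
#'   a `pet_extraction`.
#' @return A tibble with columns `lesion_id`, `modality`, `status`, `suvmax`,
#'   `threshold`, `n_voxels`, `excluded`, `reason`.
#' @export
extraction_report <- function(vois) {
  if (inherits(vois, "pet_extraction")) return(vois$report)
  rows <- purrr::map_dfr(vois, function(per_mod) {
    purrr::map_dfr(per_mod, function(v) {
      tibble(lesion_id = v$lesion_id, modality = v$modality, status = v$status,
             suvmax = v$suvmax, threshold = v$threshold, n_voxels = v$n_voxels)
    })
  })
  failed <- unique(rows$lesion_id[rows$status != "extracted"])
  rows$excluded <- rows$lesion_id %in% failed
  rows$reason <- ifelse(rows$excluded,
                        ifelse(rows$status != "extracted",
                               rows$status, "missing_modality"),
                        "")
  rows
}
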