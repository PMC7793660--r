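#' Per-class phantom parameter ranges
#'
#' One entry of a cohort design's effect map: the uniform ranges from which a
#' lesion of that class draws its ellipsoid semi-axes, mean uptake, and
#' heterogeneity amplitude.
#'
#' @param radius_mm Length-2 range (mm) for each ellipsoid semi-axis.
#' @param mean_suv Length-2 range for the lesion mean SUV.
#' @param heterogeneity Length-2 range for the heterogeneity amplitude.
#' @return A `phantom_params` list.
#' @export
phantom_params <- function(radius_mm, mean_suv = c(6, 10),
                           heterogeneity = c(0.2, 0.4)) {
  rng <- function(x, what) {
    if (length(x) == 1L) x <- c(x, x)
    if (length(x) != 2L || x[1] > x[2]) stop_pettex("`%s` must be a (lo, hi) range", what)
    as.numeric(x)
  }
  structure(list(radius_mm = rng(radius_mm, "radius_mm"),
                 mean_suv = rng(mean_suv, "mean_suv"),
                 heterogeneity = rng(heterogeneity, "heterogeneity")),
            class = "phantom_params")
}

default_t_effect_map <- function() {
  # Semi-axis ranges loosely follow AJCC T sizes (T1 <= 2 cm diameter,
  # T2 2-5 cm), scaled to stay inside a desk-scale field of view.
  list(
    "Tis" = phantom_params(radius_mm = c(3, 5)),
    "T1"  = phantom_params(radius_mm = c(5, 9)),
    "T2"  = phantom_params(radius_mm = c(9, 15)),
    "T3"  = phantom_params(radius_mm = c(15, 18))
  )
}

# Label vocabularies for the four tumor characteristics.
label_vocab <- list(
  T_category = c("Tis", "T1", "T2", "T3", "T4"),
  N_category = c("N0", "N1", "N2", "N3"),
  subtype = c("Luminal A", "Luminal B/HER2-", "Luminal B/HER2+",
              "HER2", "Triple-negative"),
  ki67 = c("<20%", ">=20%", "unspecified")
)

# Default composition of the nuisance (no-effect) labels, mirroring a
# realistic breast-cancer cohort mix.
default_nuisance_props <- function() {
  list(
    N_category = c("N0" = 0.50, "N1" = 0.30, "N2" = 0.14, "N3" = 0.06),
    subtype = c("Luminal A" = 0.43, "Luminal B/HER2-" = 0.34,
                "Luminal B/HER2+" = 0.05, "HER2" = 0.07, "Triple-negative" = 0.11),
    ki67 = c("<20%" = 0.32, ">=20%" = 0.59, "unspecified" = 0.09)
  )
}

#' Synthetic cohort design
#'
#' Describes a labeled synthetic cohort: how many lesions, which tumor
#' characteristic drives the phantom parameters (the driver label), the class
#' proportions of that label, and per-class phantom parameter ranges (the
#' effect map). The remaining characteristics are assigned independently of
#' the phantoms from realistic cohort proportions, i.e. they carry no signal.
#'
#' @param n_lesions Number of lesions (>= 2 per driver class).
#' @param label_name Driver label column; one of `"T_category"`,
#'   `"N_category"`, `"subtype"`, `"ki67"`.
#' @param classes Named vector of driver-class proportions (sums to 1; names
#'   must belong to the label's vocabulary).
#' @param effect_map Named list of [phantom_params()], one per driver class.
#' @param background_suv,noise_sd_suv,heterogeneity_correlation_length_mm,fov_mm
#'   Cohort-wide phantom settings (see [phantom_spec()]).
#' @param nuisance_props Named list of proportion vectors for the non-driver
#'   labels.
#' @param seed Master seed; per-lesion seeds are derived deterministically.
#' @return A `cohort_design` object.
#' @examples
#' design <- cohort_design(n_lesions = 8, seed = 7,
#'                         classes = c(T1 = 0.5, T2 = 0.5),
#'                         fov_mm = c(40, 40, 40))
#' @export
cohort_design <- function(n_lesions = 44,
                          label_name = "T_category",
                          classes = c("Tis" = 4, "T1" = 12, "T2" = 25, "T3" = 3) / 44,
                          effect_map = default_t_effect_map()[names(classes)],
                          background_suv = 0.8,
                          noise_sd_suv = 0.05,
                          heterogeneity_correlation_length_mm = 1.5,
                          fov_mm = c(56, 56, 56),
                          nuisance_props = default_nuisance_props(),
                          seed = NULL) {
  if (is.null(seed)) stop_pettex("`seed` is mandatory for a cohort design")
  if (!label_name %in% names(label_vocab)) {
    stop_pettex("unknown label `%s`", label_name)
  }
  if (is.null(names(classes)) || !all(names(classes) %in% label_vocab[[label_name]])) {
    stop_pettex("class names must belong to the %s vocabulary", label_name)
  }
  if (abs(sum(classes) - 1) > 1e-6) stop_pettex("class proportions must sum to 1")
  if (any(classes <= 0)) stop_pettex("empty class in design: %s",
                                     paste(names(classes)[classes <= 0], collapse = ", "))
  if (!setequal(names(effect_map), names(classes))) {
    stop_pettex("`effect_map` must have one entry per class")
  }
  counts <- round(classes * n_lesions)
  counts[which.max(counts)] <- counts[which.max(counts)] + (n_lesions - sum(counts))
  if (n_lesions < 2 || any(counts < 2)) {
    stop_pettex("each driver class needs at least 2 lesions (got: %s)",
                paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  }
  structure(
    list(n_lesions = as.integer(n_lesions), label_name = label_name,
         classes = classes, class_counts = counts, effect_map = effect_map,
         background_suv = background_suv, noise_sd_suv = noise_sd_suv,
         heterogeneity_correlation_length_mm = heterogeneity_correlation_length_mm,
         fov_mm = check_length3(fov_mm, "fov_mm"),
         nuisance_props = nuisance_props, seed = as.integer(seed)),
    class = "cohort_design"
  )
}

#' Generate a paired-modality synthetic cohort
#'
#' Draws one [phantom_spec()] per lesion from its driver class's parameter
#' ranges, renders the ground truth once, and images it with every modality
#' profile, so both modality volumes of a lesion derive from the same ground
#' truth. Returns the volumes together with a label table carrying all four
#' tumor-characteristic columns (driver + nuisance).
#'
#' @param design A [cohort_design()].
#' @param profiles List of [modality_profile()]s (default dbPET + wbPET).
#' @param grid_spacing_mm Ground-truth grid spacing (mm).
#' @param keep_truth Keep the fine-grid truth volumes (memory-heavy).
#' @return A `pet_cohort`: list with `lesions` (per lesion: `spec`, `volumes`
#'   per modality), `labels` (tibble), `design`, `profiles`.
#' @examples
#' design <- cohort_design(n_lesions = 4, seed = 1,
#'                         classes = c(T1 = 0.5, T2 = 0.5),
#'                         fov_mm = c(40, 40, 40))
#' cohort <- generate_cohort(design)
#' cohort$labels
#' @export
generate_cohort <- function(design, profiles = default_profiles(),
                            grid_spacing_mm = c(0.5, 0.5, 0.5),
                            keep_truth = FALSE) {
  stopifnot(inherits(design, "cohort_design"))
  if (design$n_lesions == 0) stop_pettex("empty cohort design")
  n <- design$n_lesions
  if (is.null(names(profiles))) {
    names(profiles) <- vapply(profiles, function(p) p$name, character(1))
  }

  draws <- with_local_seed(design$seed, {
    driver <- sample(rep(names(design$class_counts), design$class_counts))
    nuis <- lapply(names(design$nuisance_props), function(lab) {
      p <- design$nuisance_props[[lab]]
      sample(names(p), n, replace = TRUE, prob = p)
    })
    names(nuis) <- names(design$nuisance_props)
    params <- lapply(seq_len(n), function(i) {
      pp <- design$effect_map[[driver[i]]]
      list(radii = runif(3, pp$radius_mm[1], pp$radius_mm[2]),
           mean_suv = runif(1, pp$mean_suv[1], pp$mean_suv[2]),
           het = runif(1, pp$heterogeneity[1], pp$heterogeneity[2]))
    })
    seeds <- sample.int(.Machine$integer.max - 2L, n * (1 + length(profiles)))
    list(driver = driver, nuis = nuis, params = params,
         seeds = matrix(seeds, nrow = n))
  })

  ids <- sprintf("L%03d", seq_len(n))
  lesions <- vector("list", n)
  names(lesions) <- ids
  for (i in seq_len(n)) {
    p <- draws$params[[i]]
    spec <- phantom_spec(
      lesion_radii_mm = p$radii,
      lesion_mean_suv = p$mean_suv,
      background_suv = design$background_suv,
      heterogeneity_amplitude = p$het,
      heterogeneity_correlation_length_mm = design$heterogeneity_correlation_length_mm,
      noise_sd_suv = design$noise_sd_suv,
      fov_mm = design$fov_mm,
      seed = draws$seeds[i, 1]
    )
    truth <- render_ground_truth(spec, grid_spacing_mm)
    truth$lesion_id <- ids[i]
    volumes <- lapply(seq_along(profiles), function(j) {
      image_with_modality(truth, profiles[[j]],
                          noise_sd_suv = design$noise_sd_suv,
                          seed = draws$seeds[i, 1 + j])
    })
    names(volumes) <- names(profiles)
    lesions[[i]] <- list(lesion_id = ids[i], spec = spec, volumes = volumes,
                         truth = if (keep_truth) truth else NULL)
  }

  labels <- tibble(lesion_id = ids)
  labels[[design$label_name]] <- draws$driver
  for (lab in names(draws$nuis)) {
    if (!lab %in% names(labels)) labels[[lab]] <- draws$nuis[[lab]]
  }
  for (lab in names(label_vocab)) {
    if (!lab %in% names(labels)) labels[[lab]] <- NA_character_
  }

  structure(list(lesions = lesions, labels = labels, design = design,
                 profiles = profiles),
            class = "pet_cohort")
}

#' @export
print.pet_cohort <- function(x, ...) {
  cat(sprintf("<pet_cohort> %d lesions x %d modalities (driver: %s)\n",
              length(x$lesions), length(x$profiles), x$design$label_name))
  print(table(x$labels[[x$design$label_name]]))
  invisible(x)
}
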