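# Gray-level quantization and the four 3D texture matrices.
#
# All matrices operate on a `quantized_lesion`: integer gray levels 1..G on
# the lesion mask only (out-of-mask voxels never enter any matrix). Offsets
# are taken in index space; on anisotropic grids a "neighbor" is therefore a
# grid neighbor, not an equidistant physical neighbor — the common convention
# of radiomics engines, noted as a limitation for cross-grid comparisons.

#' Quantize in-mask SUVs to G gray levels
#'
#' Fixed-bin-number quantization over the in-mask SUV range (64 discrete
#' values from the lowest to the highest SUV, by default):
#' `level(v) = min(G, floor((v - min) / (max - min) * G) + 1)`.
#' A lesion with zero in-mask range maps entirely to level 1.
#'
#' @param volume An [suv_volume()].
#' @param voi An extracted `lesion_voi` from [extract_lesion()].
#' @param G Number of gray levels (default 64).
#' @return A `quantized_lesion`: integer `levels` array cropped to the mask
#'   bounding box (`NA` outside the mask), `G`, `suv_min`, `suv_max`,
#'   `raw_suv` (in-mask SUVs), `n_voxels`, `spacing_mm`.
#' @export
quantize <- function(volume, voi, G = 64L) {
  stopifnot(inherits(volume, "suv_volume"), inherits(voi, "lesion_voi"))
  if (voi$status != "extracted" || voi$n_voxels == 0) {
    stop_pettex("cannot quantize a lesion with status `%s`", voi$status)
  }
  G <- as.integer(G)
  if (G < 2) stop_pettex("`G` must be at least 2")
  mask <- voi$mask
  idx <- which(mask, arr.ind = TRUE)
  rng <- apply(idx, 2, range)
  sub <- function(a) a[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2],
                       rng[1, 3]:rng[2, 3], drop = FALSE]
  vals <- sub(volume$values)
  m <- sub(mask)
  suv <- vals[m]
  suv_min <- min(suv)
  suv_max <- max(suv)
  levels <- array(NA_integer_, dim(vals))
  if (suv_max > suv_min) {
    levels[m] <- pmin(G, floor((vals[m] - suv_min) / (suv_max - suv_min) * G) + 1L)
  } else {
    levels[m] <- 1L
  }
  structure(
    list(levels = levels, G = G, suv_min = suv_min, suv_max = suv_max,
         raw_suv = suv, n_voxels = length(suv), spacing_mm = volume$spacing_mm),
    class = "quantized_lesion"
  )
}

#' Build a quantized lesion directly from a gray-level array
#'
#' Constructs a `quantized_lesion` from an integer level array (`NA` marks
#' out-of-mask voxels), bypassing delineation and quantization — useful for
#' testing texture formulas on hand-built patterns. Raw SUVs default to the
#' levels themselves.
#'
#' @param levels 3D integer array of gray levels, `NA` outside the mask.
#' @param G Number of gray levels.
#' @param spacing_mm Voxel spacing (mm).
#' @param raw_suv Optional raw SUVs of the in-mask voxels.
#' @return A `quantized_lesion`.
#' @export
as_quantized <- function(levels, G = max(levels, na.rm = TRUE),
                         spacing_mm = c(1, 1, 1), raw_suv = NULL) {
  if (!is.array(levels) || length(dim(levels)) != 3L) {
    stop_pettex("`levels` must be a 3D array")
  }
  suv <- if (is.null(raw_suv)) as.numeric(levels[!is.na(levels)]) else raw_suv
  structure(
    list(levels = array(as.integer(levels), dim(levels)), G = as.integer(G),
         suv_min = min(suv), suv_max = max(suv), raw_suv = suv,
         n_voxels = sum(!is.na(levels)), spacing_mm = spacing_mm),
    class = "quantized_lesion"
  )
}

# Linear-index arrays of the two overlapping subarrays displaced by `o`.
shift_indices <- function(dims, o) {
  r <- lapply(1:3, function(k) {
    lo <- max(1, 1 - o[k])
    hi <- min(dims[k], dims[k] - o[k])
    src <- if (lo > hi) integer(0) else lo:hi
    list(src = src, dst = src + o[k])
  })
  if (any(vapply(r, function(z) length(z$src) == 0, logical(1)))) {
    return(list(src = integer(0), dst = integer(0)))
  }
  L <- array(seq_len(prod(dims)), dims)
  list(src = as.vector(L[r[[1]]$src, r[[2]]$src, r[[3]]$src, drop = FALSE]),
       dst = as.vector(L[r[[1]]$dst, r[[2]]$dst, r[[3]]$dst, drop = FALSE]))
}

#' Gray-level co-occurrence matrix (GLCM)
#'
#' Symmetric co-occurrence counts of gray-level pairs over the given index
#' offsets (default: the 13 unique 3D directions at Chebyshev distance 1),
#' counting only voxel pairs that both lie inside the mask. Matrices are
#' merged (summed) across directions.
#'
#' @param q A `quantized_lesion`.
#' @param directions Integer matrix of direction offsets (rows).
#' @param distance Offset multiplier in voxels (default 1).
#' @return A `G x G` count matrix.
#' @export
glcm_matrix <- function(q, directions = offsets13(), distance = 1L) {
  lv <- q$levels
  G <- q$G
  counts <- matrix(0, G, G)
  for (r in seq_len(nrow(directions))) {
    si <- shift_indices(dim(lv), directions[r, ] * distance)
    a <- lv[si$src]
    b <- lv[si$dst]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    tab <- tabulate((a[ok] - 1L) * G + b[ok], nbins = G * G)
    counts <- counts + matrix(tab, G, G, byrow = TRUE)
  }
  counts + t(counts)
}

#' Gray-level run-length matrix (GLRLM)
#'
#' Counts of maximal runs of equal gray level along each direction, restricted
#' to the mask and merged across directions.
#'
#' @inheritParams glcm_matrix
#' @return A `G x max_run` count matrix (`r[i, j]` = number of runs of gray
#'   level `i` and length `j`).
#' @export
glrlm_matrix <- function(q, directions = offsets13()) {
  lv <- q$levels
  G <- q$G
  dims <- dim(lv)
  coords <- which(!is.na(lv), arr.ind = TRUE)
  levels <- lv[!is.na(lv)]
  maxd <- max(dims)
  B <- 2 * maxd + 4
  counts <- matrix(0, G, maxd)
  for (r in seq_len(nrow(directions))) {
    o <- directions[r, ]
    fa <- which(o != 0)[1]
    t <- coords[, fa]
    a1 <- coords[, 1] - t * o[1]
    a2 <- coords[, 2] - t * o[2]
    a3 <- coords[, 3] - t * o[3]
    key <- ((a1 + maxd + 2) * B + (a2 + maxd + 2)) * B + (a3 + maxd + 2)
    ord <- order(key, t)
    k <- key[ord]; tt <- t[ord]; le <- levels[ord]
    n <- length(k)
    new_run <- c(TRUE, k[-1] != k[-n] | tt[-1] != tt[-n] + 1L | le[-1] != le[-n])
    runid <- cumsum(new_run)
    lens <- tabulate(runid)
    rlev <- le[new_run]
    tab <- tabulate((rlev - 1L) * maxd + lens, nbins = G * maxd)
    counts <- counts + matrix(tab, G, maxd, byrow = TRUE)
  }
  last <- max(which(colSums(counts) > 0))
  counts[, seq_len(last), drop = FALSE]
}

#' Gray-level zone-size matrix (GLZSM)
#'
#' Zones are 26-connected components of equal gray level within the mask; the
#' matrix counts zones by (gray level, zone size).
#'
#' @param q A `quantized_lesion`.
#' @return A `G x max_zone_size` count matrix.
#' @export
glzsm_matrix <- function(q) {
  lv <- q$levels
  G <- q$G
  coords <- which(!is.na(lv), arr.ind = TRUE)
  levels <- lv[!is.na(lv)]
  pairs <- adjacency_pairs_26(coords)
  if (nrow(pairs) > 0) {
    pairs <- pairs[levels[pairs[, 1]] == levels[pairs[, 2]], , drop = FALSE]
  }
  g <- igraph::make_empty_graph(n = nrow(coords), directed = FALSE)
  if (nrow(pairs) > 0) g <- igraph::add_edges(g, t(pairs))
  memb <- igraph::components(g)$membership
  sizes <- tabulate(memb)
  zone_level <- levels[match(seq_along(sizes), memb)]
  smax <- max(sizes)
  counts <- matrix(0, G, smax)
  tab <- tabulate((zone_level - 1L) * smax + sizes, nbins = G * smax)
  counts + matrix(tab, G, smax, byrow = TRUE)
}

#' Neighborhood gray-level difference accumulators (NGLDM)
#'
#' For every in-mask voxel with at least one in-mask 26-neighbor, the absolute
#' difference between its gray level and the mean gray level of its in-mask
#' neighbors (center excluded) is accumulated per gray level.
#'
#' @param q A `quantized_lesion`.
#' @return A list with `s` (per-level accumulated absolute differences), `n`
#'   (per-level voxel counts), and `n_valid` (voxels with >= 1 neighbor).
#' @export
ngldm_matrix <- function(q) {
  lv <- q$levels
  dims <- dim(lv)
  nbr_sum <- array(0, dims)
  nbr_cnt <- array(0L, dims)
  offs <- offsets13()
  for (r in seq_len(nrow(offs))) {
    si <- shift_indices(dims, offs[r, ])
    a <- lv[si$src]
    b <- lv[si$dst]
    ok <- which(!is.na(a) & !is.na(b))
    if (length(ok) == 0) next
    s <- si$src[ok]; d <- si$dst[ok]
    nbr_sum[d] <- nbr_sum[d] + a[ok]
    nbr_cnt[d] <- nbr_cnt[d] + 1L
    nbr_sum[s] <- nbr_sum[s] + b[ok]
    nbr_cnt[s] <- nbr_cnt[s] + 1L
  }
  valid <- !is.na(lv) & nbr_cnt > 0
  if (!any(valid)) stop_pettex("no in-mask voxel has an in-mask neighbor")
  diffs <- abs(lv[valid] - nbr_sum[valid] / nbr_cnt[valid])
  levs <- lv[valid]
  s <- vapply(seq_len(q$G), function(i) sum(diffs[levs == i]), numeric(1))
  n <- tabulate(levs, nbins = q$G)
  list(s = s, n = n, n_valid = sum(valid))
}
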