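# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_pettex <- function(...) stop(sprintf(...), call. = FALSE)

check_length3 <- function(x, what) {
  if (!is.numeric(x) || length(x) != 3L || anyNA(x)) {
    stop_pettex("`%s` must be a numeric 3-vector", what)
  }
  as.numeric(x)
}

axis_names <- c("x", "y", "z")

# Run `expr` under a private RNG stream; the global RNG state is untouched.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

# Deterministically derive `n` sub-seeds (< 2^31) from one master seed.
derive_seeds <- function(seed, n) {
  with_local_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Physical coordinates of voxel centers along one axis.
# Convention: the center of voxel 1 (R index) sits at 0 mm, so index i -> (i-1)*spacing.
axis_coords <- function(n, spacing) (seq_len(n) - 1) * spacing

# Squared-distance field from `center` (mm) over a grid, as a 3D array.
dist2_array <- function(dim, spacing, center, scale = c(1, 1, 1)) {
  a1 <- ((axis_coords(dim[1], spacing[1]) - center[1]) / scale[1])^2
  a2 <- ((axis_coords(dim[2], spacing[2]) - center[2]) / scale[2])^2
  a3 <- ((axis_coords(dim[3], spacing[3]) - center[3]) / scale[3])^2
  outer(outer(a1, a2, "+"), a3, "+")
}
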