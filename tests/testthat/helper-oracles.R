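# Independent brute-force oracles. These deliberately share no code with the
# package implementations: plain voxel-by-voxel loops, recursive flood fills,
# pair enumeration, and exhaustive permutation enumeration.

all_offsets_26 <- local({
  m <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  unname(m[rowSums(abs(m)) > 0, , drop = FALSE])
})

half_offsets_13 <- local({
  keep <- apply(all_offsets_26, 1, function(o) o[which(o != 0)[1]] > 0)
  all_offsets_26[keep, , drop = FALSE]
})

oracle_glcm <- function(lv, dirs, G) {
  d <- dim(lv)
  M <- matrix(0, G, G)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lv[x, y, z]
    if (is.na(a)) next
    for (r in seq_len(nrow(dirs))) for (sg in c(1L, -1L)) {
      p <- c(x, y, z) + sg * dirs[r, ]
      if (any(p < 1) || any(p > d)) next
      b <- lv[p[1], p[2], p[3]]
      if (!is.na(b)) M[a, b] <- M[a, b] + 1
    }
  }
  M
}

oracle_glrlm <- function(lv, dirs, G) {
  d <- dim(lv)
  M <- matrix(0, G, 3 * max(d))
  inb <- function(p) all(p >= 1) && all(p <= d)
  val <- function(p) lv[p[1], p[2], p[3]]
  for (r in seq_len(nrow(dirs))) {
    o <- dirs[r, ]
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      p <- c(x, y, z)
      a <- val(p)
      if (is.na(a)) next
      q <- p - o
      if (inb(q) && !is.na(val(q)) && val(q) == a) next  # not a run start
      len <- 1L
      q <- p + o
      while (inb(q) && !is.na(val(q)) && val(q) == a) {
        len <- len + 1L
        q <- q + o
      }
      M[a, len] <- M[a, len] + 1
    }
  }
  M[, seq_len(max(which(colSums(M) > 0))), drop = FALSE]
}

oracle_glzsm <- function(lv, G) {
  d <- dim(lv)
  seen <- array(FALSE, d)
  zones <- matrix(0, 0, 2)
  coords <- which(!is.na(lv), arr.ind = TRUE)
  for (i in seq_len(nrow(coords))) {
    p0 <- coords[i, ]
    if (seen[p0[1], p0[2], p0[3]]) next
    a <- lv[p0[1], p0[2], p0[3]]
    stack <- list(p0)
    seen[p0[1], p0[2], p0[3]] <- TRUE
    size <- 0L
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1L
      for (r in seq_len(nrow(all_offsets_26))) {
        q <- p + all_offsets_26[r, ]
        if (any(q < 1) || any(q > d) || seen[q[1], q[2], q[3]]) next
        b <- lv[q[1], q[2], q[3]]
        if (!is.na(b) && b == a) {
          seen[q[1], q[2], q[3]] <- TRUE
          stack[[length(stack) + 1L]] <- q
        }
      }
    }
    zones <- rbind(zones, c(a, size))
  }
  M <- matrix(0, G, max(zones[, 2]))
  for (j in seq_len(nrow(zones))) {
    M[zones[j, 1], zones[j, 2]] <- M[zones[j, 1], zones[j, 2]] + 1
  }
  M
}

oracle_ngldm <- function(lv, G) {
  d <- dim(lv)
  s <- numeric(G)
  n <- integer(G)
  n_valid <- 0L
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lv[x, y, z]
    if (is.na(a)) next
    nb <- c()
    for (r in seq_len(nrow(all_offsets_26))) {
      p <- c(x, y, z) + all_offsets_26[r, ]
      if (any(p < 1) || any(p > d)) next
      b <- lv[p[1], p[2], p[3]]
      if (!is.na(b)) nb <- c(nb, b)
    }
    if (length(nb) == 0) next
    n_valid <- n_valid + 1L
    s[a] <- s[a] + abs(a - mean(nb))
    n[a] <- n[a] + 1L
  }
  list(s = s, n = n, n_valid = n_valid)
}

# 26-connected flood fill over a logical candidate array, from a linear index.
oracle_flood <- function(cand, start_idx) {
  d <- dim(cand)
  out <- array(FALSE, d)
  p0 <- which(array(seq_along(cand), d) == start_idx, arr.ind = TRUE)[1, ]
  if (!cand[p0[1], p0[2], p0[3]]) return(out)
  stack <- list(p0)
  out[p0[1], p0[2], p0[3]] <- TRUE
  while (length(stack) > 0) {
    p <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    for (r in seq_len(nrow(all_offsets_26))) {
      q <- p + all_offsets_26[r, ]
      if (any(q < 1) || any(q > d)) next
      if (cand[q[1], q[2], q[3]] && !out[q[1], q[2], q[3]]) {
        out[q[1], q[2], q[3]] <- TRUE
        stack[[length(stack) + 1L]] <- q
      }
    }
  }
  out
}

# AUC as the pairwise concordance fraction, ties counted 1/2.
oracle_auc <- function(y, s) {
  s0 <- s[y == 0]
  s1 <- s[y == 1]
  cmp <- outer(s1, s0, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Exact two-sided rank-sum p-value by full enumeration of group assignments.
oracle_ranksum_p <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(length(pooled), nx)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# Random masked quantized volume for oracle-equivalence checks.
random_quantized <- function(dims = c(5, 5, 5), G = 4, p_mask = 0.7) {
  lv <- array(sample.int(G, prod(dims), replace = TRUE), dims)
  lv[runif(prod(dims)) > p_mask] <- NA_integer_
  if (all(is.na(lv))) lv[1, 1, 1] <- 1L
  as_quantized(lv, G = G)
}
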