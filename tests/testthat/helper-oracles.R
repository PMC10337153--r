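# Independent oracles and small fixture builders. These re-derive expected
# values by brute force or closed form, never through the code paths they
# check.

# Closed-form algebraic least-squares sphere fit (linear in the Kasa/Coope
# parameterization): minimize ||x^2+y^2+z^2 - 2ax - 2by - 2cz - k||^2.
coope_sphere_fit <- function(pts) {
  A <- cbind(2 * pts, 1)
  rhs <- rowSums(pts^2)
  beta <- qr.solve(A, rhs)
  ctr <- beta[1:3]
  r <- sqrt(beta[4] + sum(ctr^2))
  list(center = ctr, r = r)
}

# Exhaustive Otsu: try every inter-bin cut, score between-class variance
# directly from the two voxel groups.
brute_force_otsu <- function(arr, bins = 256L) {
  lo <- min(arr); hi <- max(arr)
  idx <- pmin(floor((arr - lo) / (hi - lo) * bins), bins - 1L)
  lev <- as.vector(idx)
  best <- -Inf; best_k <- NA_integer_
  for (k in 0:(bins - 2L)) {
    g0 <- lev[lev <= k]; g1 <- lev[lev > k]
    if (!length(g0) || !length(g1)) next
    w0 <- length(g0) / length(lev); w1 <- 1 - w0
    s <- w0 * w1 * (mean(g0) - mean(g1))^2
    if (s > best) { best <- s; best_k <- k }
  }
  lo + (best_k + 1) / bins * (hi - lo)
}

# Per-column loop maximum-intensity projection.
brute_force_mip <- function(arr3) {
  d <- dim(arr3)
  out <- matrix(-Inf, d[1L], d[2L])
  for (i in seq_len(d[1L])) {
    for (j in seq_len(d[2L])) {
      for (k in seq_len(d[3L])) out[i, j] <- max(out[i, j], arr3[i, j, k])
    }
  }
  out
}

# random integer-valued test volume
rand_volume <- function(dims, seed, max_val = 255, dtype = "uint8") {
  set.seed(seed)
  volume_stack(array(sample(0:max_val, prod(dims), replace = TRUE), dims), dtype = dtype)
}

# voxel coordinates (0-based) of foreground in a 3-D array
fg_coords <- function(arr3, tau) {
  which(arr3 > tau, arr.ind = TRUE) - 1
}

# add n salt (bright outlier) voxels at background positions, seeded
add_salt <- function(volume, n, value = 255, seed = 1) {
  arr <- sub_volume(volume)
  set.seed(seed)
  bg <- which(arr == 0)
  arr[sample(bg, n)] <- value
  volume_stack(arr, dtype = "float")
}
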