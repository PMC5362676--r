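# Independent brute-force oracles, deliberately written as plain per-voxel
# loops so they share no code with the package's vectorized implementations.

# Forward-difference Jacobian matrix at one voxel by direct indexing with
# boundary replication.
oracle_jacobian_at <- function(field, i1, i2, i3) {
  n <- field$domain$shape
  comps <- list(field$d1, field$d2, field$d3)
  J <- diag(3)
  for (i in 1:3) for (j in 1:3) {
    nb <- c(i1, i2, i3)
    if (nb[j] < n[j]) nb[j] <- nb[j] + 1  # else replicate: difference 0
    J[i, j] <- J[i, j] + comps[[i]][nb[1], nb[2], nb[3]] -
      comps[[i]][i1, i2, i3]
  }
  J
}

# Full determinant image via the per-voxel loop oracle.
oracle_det_image <- function(field) {
  n <- field$domain$shape
  out <- array(NA_real_, dim = n)
  for (i3 in 1:n[3]) for (i2 in 1:n[2]) for (i1 in 1:n[1])
    out[i1, i2, i3] <- det(oracle_jacobian_at(field, i1, i2, i3))
  out
}

# Direct nested-loop Gaussian convolution with a truncated product kernel,
# renormalized per voxel over in-grid (and in-mask) neighbors.
oracle_gaussian_smooth <- function(values, sigma, mask = NULL) {
  n <- dim(values)
  if (is.null(mask)) mask <- array(TRUE, dim = n)
  r <- max(1, ceiling(4 * sigma))
  out <- array(NA_real_, dim = n)
  for (i3 in 1:n[3]) for (i2 in 1:n[2]) for (i1 in 1:n[1]) {
    if (!mask[i1, i2, i3]) next
    acc <- 0; wsum <- 0
    for (o3 in -r:r) for (o2 in -r:r) for (o1 in -r:r) {
      j <- c(i1 + o1, i2 + o2, i3 + o3)
      if (any(j < 1) || any(j > n) || !mask[j[1], j[2], j[3]]) next
      w <- exp(-(o1^2 + o2^2 + o3^2) / (2 * sigma^2))
      acc <- acc + w * values[j[1], j[2], j[3]]
      wsum <- wsum + w
    }
    out[i1, i2, i3] <- acc / wsum
  }
  out
}

# Dense loop-built 7-point Neumann Laplacian matrix.
oracle_dense_laplacian <- function(shape) {
  N <- prod(shape)
  lin <- function(i) i[1] + shape[1] * (i[2] - 1) + shape[1] * shape[2] * (i[3] - 1)
  A <- matrix(0, N, N)
  for (i3 in 1:shape[3]) for (i2 in 1:shape[2]) for (i1 in 1:shape[1]) {
    k <- lin(c(i1, i2, i3))
    for (ax in 1:3) for (s in c(-1, 1)) {
      nb <- c(i1, i2, i3); nb[ax] <- nb[ax] + s
      if (nb[ax] >= 1 && nb[ax] <= shape[ax]) {
        A[k, lin(nb)] <- A[k, lin(nb)] + 1
        A[k, k] <- A[k, k] - 1
      }  # replicated ghost: no contribution
    }
  }
  A
}

# A small reproducible smooth random field for generic tests.
smooth_test_field <- function(shape = c(8, 8, 8), seed = 1, amplitude = 0.3) {
  make_noise_field(grid_domain(shape), sigma = 1.5, amplitude = amplitude,
                   seed = seed, require_positive = FALSE)
}
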