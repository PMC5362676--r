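#' Affine displacement field with known Jacobian determinant
#'
#' d(x) = (M - I) x + b in 0-based voxel coordinates, so phi(x) = M x + b.
#' The forward-difference Jacobian is exact for affine transformations, so
#' det(M) is the ground-truth determinant at every voxel with in-grid
#' forward neighbors.
#'
#' @param M 3x3 matrix with positive determinant.
#' @param b numeric 3-vector offset (voxel units).
#' @param domain a [grid_domain()].
#' @return A list: `field` ([displacement_field()]) and `det` (det(M)).
#' @export
make_affine_field <- function(M, b, domain) {
  M <- matrix(as.numeric(M), 3, 3)
  dM <- det(M)
  if (!is.finite(dM) || dM <= 0)
    stop("affine map must have positive determinant (diffeomorphic)")
  co <- coordinate_arrays(domain)
  A <- M - diag(3)
  comps <- lapply(1:3, function(i)
    A[i, 1] * co$x1 + A[i, 2] * co$x2 + A[i, 3] * co$x3 + b[i])
  list(field = displacement_field(domain, comps[[1]], comps[[2]], comps[[3]]),
       det = dM)
}

#' Separable sinusoidal displacement field with closed-form Jacobian
#'
#' Component j depends only on coordinate j:
#' d^(j)(x) = a_j sin(2 pi f_j x_j / n_j), a smooth nonlinear analogue of
#' non-uniform respiratory motion.  The continuous Jacobian is diagonal,
#' with determinant prod_j (1 + a_j (2 pi f_j / n_j) cos(2 pi f_j x_j / n_j)),
#' returned as a closed-form evaluator.  Amplitudes are validated so the
#' continuous determinant stays strictly positive; the discrete
#' forward-difference determinant converges to the continuous one at first
#' order in the grid spacing.
#'
#' @param amplitudes numeric 3-vector a (voxel units).
#' @param frequencies numeric 3-vector f (cycles across the grid extent).
#' @param domain a [grid_domain()].
#' @return A list: `field`, and `det_fun(points)` evaluating the continuous
#'   determinant at 0-based points (n x 3 matrix).
#' @export
make_sinusoid_field <- function(amplitudes, frequencies, domain) {
  a <- as.numeric(amplitudes); f <- as.numeric(frequencies)
  n <- domain$shape
  w <- 2 * pi * f / n
  if (any(abs(a * w) >= 1)) {
    j <- which.max(abs(a * w))
    stop(sprintf("amplitude*frequency too large along axis %d (|a*2*pi*f/n| = %.3f >= 1): continuous determinant not strictly positive",
                 j, abs(a[j] * w[j])))
  }
  co <- coordinate_arrays(domain)
  xs <- list(co$x1, co$x2, co$x3)
  comps <- lapply(1:3, function(j) a[j] * sin(w[j] * xs[[j]]))
  field <- displacement_field(domain, comps[[1]], comps[[2]], comps[[3]])
  det_img <- jacobian_determinant(forward_jacobian(field))
  if (any(det_img$values <= 0)) {
    bad <- which(det_img$values <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("discrete determinant nonpositive at voxel (%d,%d,%d)",
                 bad[1], bad[2], bad[3]))
  }
  det_fun <- function(points) {
    points <- matrix(as.numeric(points), ncol = 3)
    out <- rep(1, nrow(points))
    for (j in 1:3) out <- out * (1 + a[j] * w[j] * cos(w[j] * points[, j]))
    out
  }
  list(field = field, det_fun = det_fun)
}

#' Smooth random displacement field (Gaussian-filtered noise)
#'
#' Each component is white Gaussian noise smoothed with a Gaussian filter
#' and rescaled to a chosen maximum absolute displacement: a generic smooth
#' random deformation for stability experiments.  When `require_positive`
#' the discrete Jacobian determinant is validated to be strictly positive
#' (diffeomorphic convention) and generation fails otherwise.
#'
#' @param domain a [grid_domain()].
#' @param sigma smoothing width in voxels (default 2).
#' @param amplitude maximum absolute displacement in voxels (default 0.5).
#' @param seed integer RNG seed.
#' @param require_positive validate det > 0 (default TRUE).
#' @return A [displacement_field()].
#' @export
make_noise_field <- function(domain, sigma = 2, amplitude = 0.5, seed = 1L,
                             require_positive = TRUE) {
  comps <- withr_local_seed(seed, lapply(1:3, function(j) {
    z <- array(stats::rnorm(n_voxels(domain)), dim = domain$shape)
    s <- convolve_separable(z, gaussian_kernel_1d(sigma))
    s / max(abs(s)) * amplitude
  }))
  field <- displacement_field(domain, comps[[1]], comps[[2]], comps[[3]])
  if (require_positive) {
    dv <- jacobian_determinant(forward_jacobian(field))$values
    if (any(dv <= 0))
      stop("generated field has nonpositive Jacobian determinant; reduce amplitude or increase sigma")
  }
  field
}

#' Functional image with an exact sample correlation to a Jacobian image
#'
#' Builds a synthetic functional image g (a stand-in for a perfusion or
#' ventilation reference scan, already aligned to the CT grid) whose sample
#' Pearson correlation with the given Jacobian image over the mask equals
#' `rho` exactly.  Seeded smooth noise is projected orthogonal to the
#' Jacobian image (Gram-Schmidt) and mixed as
#' rho * standardized(jac) + sqrt(1 - rho^2) * standardized(residual),
#' so the correlation is attained by construction, not in expectation.
#'
#' @param jac [scalar_image()], the Jacobian image to correlate with; must
#'   be non-constant on the mask.
#' @param rho target sample correlation in `[-1, 1]`.
#' @param seed integer RNG seed.
#' @param mask optional logical array overriding the domain mask.
#' @return A [scalar_image()] with `NA` outside the mask.
#' @export
make_functional_image <- function(jac, rho, seed = 1L, mask = NULL) {
  stopifnot(inherits(jac, "scalar_image"))
  if (!is.finite(rho) || abs(rho) > 1) stop("'rho' must lie in [-1, 1]")
  if (is.null(mask)) mask <- domain_mask(jac$domain)
  jv <- jac$values[mask]
  jc <- jv - mean(jv)
  if (sum(jc^2) == 0) stop("Jacobian image is constant on the mask")
  ju <- jc / sqrt(sum(jc^2))

  z <- withr_local_seed(seed, {
    raw <- array(stats::rnorm(n_voxels(jac$domain)), dim = jac$domain$shape)
    convolve_separable(raw, gaussian_kernel_1d(2))
  })[mask]
  zc <- z - mean(z)
  r <- zc - sum(zc * ju) * ju          # orthogonal to jac and to constants
  rn <- sqrt(sum(r^2))
  if (rn == 0) stop("degenerate noise draw; change the seed")
  ru <- r / rn

  gvals <- rho * ju + sqrt(1 - rho^2) * ru
  out <- array(NA_real_, dim = jac$domain$shape)
  out[mask] <- gvals
  scalar_image(jac$domain, out)
}

#' Sample noisy fidelity data from a displacement field
#'
#' Draws a seeded uniform subset of masked voxels and records the field's
#' displacement there plus isotropic Gaussian annotation noise, emulating
#' the output of an upstream registration algorithm.
#'
#' @param field a [displacement_field()].
#' @param fraction fraction of masked voxels to sample, in (0, 1].
#' @param noise_sigma per-component Gaussian noise SD in voxels.
#' @param seed integer RNG seed.
#' @return A [fidelity_data()].
#' @export
sample_fidelity <- function(field, fraction = 0.2, noise_sigma = 0.1,
                            seed = 1L) {
  if (!is.finite(fraction) || fraction <= 0 || fraction > 1)
    stop("'fraction' must be in (0, 1]")
  domain <- field$domain
  mask_idx <- which(domain_mask(domain))
  if (length(mask_idx) == 0L) stop("empty region of interest")
  m <- max(1L, round(fraction * length(mask_idx)))
  withr_local_seed(seed, {
    lin <- sort(sample(mask_idx, m))
    ind <- arrayInd(lin, domain$shape)
    y <- cbind(field$d1[lin], field$d2[lin], field$d3[lin])
    if (noise_sigma > 0)
      y <- y + matrix(stats::rnorm(3 * m, sd = noise_sigma), ncol = 3)
    fidelity_data(domain, ind, y)
  })
}

#' Synthetic landmark pairs consistent with a displacement field
#'
#' Samples continuous reference points inside the grid and maps them
#' through the field to produce target points, with optional annotation
#' noise, emulating expert-determined landmark pairs whose ground-truth
#' correspondence is the generating field.
#'
#' @param field a [displacement_field()].
#' @param count number of pairs (>= 1).
#' @param seed integer RNG seed.
#' @param noise_sigma target-point annotation noise SD in voxels.
#' @return A [landmark_set()] carrying the domain's spacing.
#' @export
make_landmarks <- function(field, count = 100L, seed = 1L, noise_sigma = 0) {
  if (count < 1L) stop("'count' must be >= 1")
  n <- field$domain$shape
  withr_local_seed(seed, {
    ref <- cbind(stats::runif(count, 0, n[1] - 1),
                 stats::runif(count, 0, n[2] - 1),
                 stats::runif(count, 0, n[3] - 1))
    tgt <- map_points(field, ref)
    if (noise_sigma > 0)
      tgt <- tgt + matrix(stats::rnorm(3 * count, sd = noise_sigma), ncol = 3)
    landmark_set(ref, tgt, field$domain$spacing)
  })
}

#' Standard synthetic contraction study case
#'
#' Builds a complete synthetic analogue of an inhale/exhale registration
#' study on a desk-scale grid: a ground-truth contraction field whose
#' Jacobian image mirrors clinically reported unconstrained statistics
#' (mean about 0.79, standard deviation calibrated to `det_sd`), noisy
#' fidelity samples at a fraction of voxels, and landmark pairs consistent
#' with the ground truth.  The ground truth is a uniform contraction
#' (det = `det_mean` exactly for the affine part) plus a seeded smooth
#' random deformation whose amplitude is calibrated so the Jacobian image
#' has the requested standard deviation over the constrained voxel set.
#'
#' @param shape grid extents (default `c(24, 24, 12)`).
#' @param spacing mm per voxel (default `c(0.97, 0.97, 2.5)`, typical
#'   thoracic CT resolution).
#' @param det_mean target mean Jacobian determinant (default 0.79).
#' @param det_sd target SD of the Jacobian image (default 0.11).
#' @param fid_fraction fidelity sampling fraction (default 0.2).
#' @param fid_noise fidelity noise SD in voxels (default 0.1).
#' @param n_landmarks number of landmark pairs (default 100).
#' @param seed integer RNG seed.
#' @return A list: `field` (ground truth), `jac` (its Jacobian image),
#'   `fidelity`, `landmarks`, `domain`, `constrained` (logical array).
#' @export
make_contraction_case <- function(shape = c(24, 24, 12),
                                  spacing = c(0.97, 0.97, 2.5),
                                  det_mean = 0.79, det_sd = 0.11,
                                  fid_fraction = 0.2, fid_noise = 0.1,
                                  n_landmarks = 100L, seed = 1L) {
  domain <- grid_domain(shape, spacing)
  bump <- make_noise_field(domain, sigma = 2, amplitude = 1, seed = seed,
                           require_positive = FALSE)
  constrained <- constrained_voxel_set(domain)
  co <- coordinate_arrays(domain)

  build <- function(s, t) displacement_field(
    domain, (s - 1) * co$x1 + t * bump$d1, (s - 1) * co$x2 + t * bump$d2,
    (s - 1) * co$x3 + t * bump$d3)
  det_stats <- function(s, t) {
    dv <- jacobian_determinant(forward_jacobian(build(s, t)))$values[constrained]
    if (any(dv <= 0)) return(c(NA_real_, NA_real_))
    c(mean(dv), stats::sd(dv))
  }
  # alternately calibrate the uniform scale (mean) and the perturbation
  # amplitude (SD) of the Jacobian image to the requested statistics
  s <- det_mean^(1 / 3); t_star <- 0
  for (pass in 1:3) {
    t_hi <- 1
    while (is.na(det_stats(s, t_hi)[2]) || det_stats(s, t_hi)[2] < det_sd) {
      t_hi <- t_hi / 2
      if (t_hi < 1e-4)
        stop("cannot reach requested Jacobian SD with a positive determinant")
    }
    t_star <- stats::uniroot(function(t) det_stats(s, t)[2] - det_sd,
                             lower = 0, upper = t_hi, tol = 1e-7)$root
    s <- stats::uniroot(function(z) det_stats(z, t_star)[1] - det_mean,
                        lower = 0.5 * s, upper = 1.5 * s, tol = 1e-7)$root
  }
  field <- build(s, t_star)
  jac <- jacobian_determinant(forward_jacobian(field))
  list(field = field, jac = jac,
       fidelity = sample_fidelity(field, fid_fraction, fid_noise,
                                  seed = seed + 1L),
       landmarks = make_landmarks(field, n_landmarks, seed = seed + 2L),
       domain = domain, constrained = constrained)
}
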