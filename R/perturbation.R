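#' Ventilation metric under a single-voxel displacement perturbation
#'
#' Evaluates the forward-difference ventilation metric at a voxel after its
#' displacement vector d(x_k) is replaced by d(x_k) - h.  Because every
#' forward-difference entry of the Jacobian at x_k contains -d(x_k), the
#' perturbation adds h to every column of the matrix (a rank-1 update
#' h 1^T), so the perturbed metric is
#' \deqn{V_h = \det(\tilde J(x_k; d) + h\,\mathbf{1}^T) - 1.}
#' At voxels whose three forward neighbors lie inside the grid this equals
#' re-evaluating the ventilation metric after the in-place substitution
#' d(x_k) <- d(x_k) - h; at boundary-replicated voxels the rank-1 form is
#' taken as the definition (replication would otherwise cancel the
#' perturbation along the replicated axes).
#'
#' @param field a [displacement_field()].
#' @param voxel 1-based voxel index triple.
#' @param h numeric 3-vector, the perturbation in voxel units.
#' @return The perturbed ventilation value (scalar).
#' @export
perturbed_metric <- function(field, voxel, h) {
  stopifnot(inherits(field, "displacement_field"))
  h <- as.numeric(h)
  if (length(h) != 3L || any(!is.finite(h))) stop("'h' must be a finite 3-vector")
  J <- jacobian_at_voxel(field, voxel)     # errors if voxel out of grid
  Jp <- J + matrix(h, 3, 3)                # h added to every column
  det(Jp) - 1
}

#' Analytic bound on the single-voxel ventilation change
#'
#' Returns the theoretical bound on |V_h - V(x_k)| for a perturbation of
#' magnitude `h_norm` applied to the displacement vector at one voxel:
#' \deqn{\frac{3\sqrt3}{2}\,\|h\| \cdot \max_i \prod_{j \ne i}
#'       \bigl(1 + \|\nabla \tilde d^{(j)}(x_k)\|\bigr),}
#' where the gradients are the discrete forward differences of the three
#' displacement components at the voxel (Euclidean norms).  Smooth fields
#' (small gradients) yield a bound close to (3*sqrt(3)/2) * ||h||; large
#' displacement gradients amplify the potential change.
#'
#' @param field a [displacement_field()].
#' @param voxel 1-based voxel index triple.
#' @param h_norm perturbation magnitude in voxels, >= 0.
#' @return The bound (scalar).
#' @export
perturbation_bound <- function(field, voxel, h_norm) {
  if (!is.finite(h_norm) || h_norm < 0) stop("'h_norm' must be >= 0")
  gnorm <- vapply(1:3, function(j)
    sqrt(sum(displacement_gradient(field, j, voxel)^2)), numeric(1))
  prods <- vapply(1:3, function(i) prod(1 + gnorm[-i]), numeric(1))
  (3 * sqrt(3) / 2) * h_norm * max(prods)
}

#' Empirical maximum ventilation change over sampled perturbations
#'
#' Monte-Carlo verification of the perturbation bound: samples `n_samples`
#' directions uniformly on the radius-`h_norm` sphere (independent standard
#' normals, normalized), always also includes the six signed axis
#' directions, and returns the largest |V_h - V(x_k)| observed together
#' with the direction attaining it.  Deterministic given `seed`.
#'
#' @param field a [displacement_field()].
#' @param voxel 1-based voxel index triple.
#' @param h_norm perturbation magnitude (> 0).
#' @param n_samples number of random directions (>= 1).
#' @param seed integer RNG seed.
#' @return A list with `max_change`, `argmax_h` (3-vector), and
#'   `unperturbed` (the ventilation value at the voxel).
#' @export
empirical_max_change <- function(field, voxel, h_norm, n_samples = 1000L,
                                 seed = 1L) {
  if (!is.finite(h_norm) || h_norm <= 0) stop("'h_norm' must be > 0")
  if (n_samples < 1L) stop("'n_samples' must be >= 1")
  J <- jacobian_at_voxel(field, voxel)
  v0 <- det(J) - 1

  H <- withr_local_seed(seed, {
    Z <- matrix(stats::rnorm(3L * n_samples), nrow = 3L)
    Z / rep(sqrt(colSums(Z^2)), each = 3L)
  })
  axes <- cbind(diag(3), -diag(3))
  H <- cbind(H, axes) * h_norm

  # det(J + h 1^T) vectorized over perturbation columns
  vh <- det3(J[1, 1] + H[1, ], J[1, 2] + H[1, ], J[1, 3] + H[1, ],
             J[2, 1] + H[2, ], J[2, 2] + H[2, ], J[2, 3] + H[2, ],
             J[3, 1] + H[3, ], J[3, 2] + H[3, ], J[3, 3] + H[3, ]) - 1
  delta <- abs(vh - v0)
  best <- which.max(delta)
  list(max_change = delta[best], argmax_h = H[, best], unperturbed = v0)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
withr_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
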