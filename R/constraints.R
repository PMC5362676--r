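#' Jacobian bound specification
#'
#' Lower/upper bounds for a contraction or expansion target Jacobian image,
#' plus the smoothing width applied after clipping.  A contraction uses
#' `LB >= 0, UB = 1` (every voxel shrinks or keeps its volume); an
#' expansion uses `UB > LB >= 1`.  `LB = 0` is allowed but flagged: a
#' diffeomorphic target requires a strictly positive lower bound.
#'
#' @param LB lower bound, >= 0.
#' @param UB upper bound, > LB.
#' @param sigma Gaussian smoothing width in voxels, >= 0 (default 1).
#' @return An object of class `bound_spec`.
#' @export
bound_spec <- function(LB, UB, sigma = 1) {
  if (!is.finite(LB) || !is.finite(UB) || LB < 0 || UB <= LB)
    stop("require 0 <= LB < UB")
  if (!is.finite(sigma) || sigma < 0) stop("'sigma' must be >= 0")
  if (LB == 0)
    warning("LB = 0: target admits zero Jacobian values (non-diffeomorphic)")
  structure(list(LB = LB, UB = UB, sigma = sigma), class = "bound_spec")
}

#' Smoothed-Jacobian constraint function
#'
#' Builds a target Jacobian image f(x) as the mask-renormalized Gaussian
#' smoothing of an unconstrained solution's Jacobian determinant image:
#' the smoothest constraint consistent with the unconstrained solution.
#'
#' @param unc_jac [scalar_image()], the unconstrained Jacobian determinant
#'   image; must be strictly positive on the mask.
#' @param sigma smoothing width in voxels.
#' @param mask optional logical array overriding the domain mask.
#' @return A [scalar_image()] target, strictly positive on the mask.
#' @export
smoothed_constraint <- function(unc_jac, sigma, mask = NULL) {
  stopifnot(inherits(unc_jac, "scalar_image"))
  if (is.null(mask)) mask <- domain_mask(unc_jac$domain)
  vals <- unc_jac$values[mask]
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("unconstrained Jacobian image must be strictly positive on the mask")
  gaussian_smooth(unc_jac, sigma, mask = mask)
}

#' Clip a Jacobian image to [LB, UB]
#'
#' Three-case clip: values inside the bounds are kept, values below are set
#' to LB, values above to UB.
#'
#' @param unc_jac [scalar_image()].
#' @param spec a [bound_spec()].
#' @return A [scalar_image()] with all non-`NA` values in `[LB, UB]`.
#' @export
clip_to_bounds <- function(unc_jac, spec) {
  stopifnot(inherits(unc_jac, "scalar_image"), inherits(spec, "bound_spec"))
  scalar_image(unc_jac$domain, pmin(pmax(unc_jac$values, spec$LB), spec$UB))
}

#' Bound (contraction/expansion) constraint function
#'
#' Builds a target Jacobian image by clipping the unconstrained Jacobian
#' image to `[LB, UB]` and then applying mask-renormalized Gaussian
#' smoothing.  Because smoothing is a convex combination, the output is
#' guaranteed to stay within `[LB, UB]`.
#'
#' @inheritParams clip_to_bounds
#' @param mask optional logical array overriding the domain mask.
#' @return A [scalar_image()] target in `[LB, UB]` on the mask.
#' @export
bound_constraint <- function(unc_jac, spec, mask = NULL) {
  clipped <- clip_to_bounds(unc_jac, spec)
  gaussian_smooth(clipped, spec$sigma, mask = mask)
}

#' Least-squares linear map from a functional image to Jacobian values
#'
#' Fits `unc_jac ~ a * g + b` by ordinary least squares over masked voxels,
#' yielding the linear intensity mapping that brings the functional image
#' closest to the unconstrained Jacobian image.
#'
#' @param g [scalar_image()], the functional image (e.g. a perfusion scan
#'   resampled onto the CT grid).
#' @param unc_jac [scalar_image()], the unconstrained Jacobian image.
#' @param mask optional logical array overriding the domain mask.
#' @return An object of class `linear_map` with fields `a` (slope) and
#'   `b` (intercept).
#' @export
fit_linear_map <- function(g, unc_jac, mask = NULL) {
  stopifnot(inherits(g, "scalar_image"), inherits(unc_jac, "scalar_image"))
  if (is.null(mask)) mask <- domain_mask(g$domain)
  gv <- g$values[mask]
  jv <- unc_jac$values[mask]
  if (length(unique(gv)) < 2L)
    stop("functional image is constant on the mask: degenerate fit")
  fit <- stats::lm.fit(cbind(1, gv), jv)
  a <- unname(fit$coefficients[2]); b <- unname(fit$coefficients[1])
  if (a == 0) warning("fitted slope is 0: degenerate correlation constraint")
  structure(list(a = a, b = b), class = "linear_map")
}

#' @export
print.linear_map <- function(x, ...) {
  cat(sprintf("linear_map: f = %.6g * g + %.6g\n", x$a, x$b))
  invisible(x)
}

#' Forced-correlation constraint function
#'
#' Builds the target Jacobian image f(x) = a* g(x) + b* from a functional
#' image and a fitted [fit_linear_map()].  Any displacement field whose
#' Jacobian image equals f is, by construction, perfectly linearly
#' correlated with g (Pearson correlation sign(a*) * 1).  The result must
#' be strictly positive on the mask; non-positive voxels raise an error
#' unless an epsilon floor is requested.
#'
#' @param g [scalar_image()], the functional image.
#' @param map a `linear_map` (slope/intercept).
#' @param mask optional logical array overriding the domain mask.
#' @param eps_floor optional positive floor: values below it are raised to
#'   `eps_floor` instead of failing (default `NULL`, fail loudly).
#' @return A [scalar_image()] target, strictly positive on the mask.
#' @export
correlation_constraint <- function(g, map, mask = NULL, eps_floor = NULL) {
  stopifnot(inherits(g, "scalar_image"), inherits(map, "linear_map"))
  if (is.null(mask)) mask <- domain_mask(g$domain)
  f <- map$a * g$values + map$b
  bad <- mask & (!is.finite(f) | f <= 0)
  n_bad <- sum(bad)
  if (n_bad > 0) {
    if (is.null(eps_floor))
      stop(sprintf(
        "correlation constraint is non-positive at %d masked voxel(s); %s",
        n_bad, "a target Jacobian must be strictly positive"))
    if (!is.finite(eps_floor) || eps_floor <= 0) stop("'eps_floor' must be > 0")
    f[bad] <- eps_floor
  }
  f[!mask] <- NA_real_
  out <- scalar_image(g$domain, f)
  attr(out, "floored_voxels") <- n_bad
  out
}

#' Validate a target Jacobian image
#'
#' Report-only check that a constraint function is finite and strictly
#' positive on the mask, with summary statistics and violation counts.
#'
#' @param f [scalar_image()], the candidate target.
#' @param mask optional logical array overriding the domain mask.
#' @return A list: `ok`, `n`, `min`, `max`, `mean`, `n_nonpositive`,
#'   `n_nonfinite`, and `violations` (1-based index matrix, possibly empty).
#' @export
validate_constraint <- function(f, mask = NULL) {
  stopifnot(inherits(f, "scalar_image"))
  if (is.null(mask)) mask <- domain_mask(f$domain)
  v <- f$values
  nonfinite <- mask & !is.finite(v)
  nonpos <- mask & is.finite(v) & v <= 0
  bad <- nonfinite | nonpos
  vals <- v[mask & !nonfinite]
  list(
    ok = !any(bad),
    n = sum(mask),
    min = if (length(vals)) min(vals) else NA_real_,
    max = if (length(vals)) max(vals) else NA_real_,
    mean = if (length(vals)) mean(vals) else NA_real_,
    n_nonpositive = sum(nonpos),
    n_nonfinite = sum(nonfinite),
    violations = which(bad, arr.ind = TRUE)
  )
}
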