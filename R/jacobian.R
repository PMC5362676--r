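#' Forward-difference Jacobian matrix field
#'
#' Computes, at every voxel, the 3x3 Jacobian matrix of the transformation
#' phi(x) = x + d(x) using one-sided forward differences under the unit-voxel
#' convention: entry (i, j) is
#' \deqn{\delta_{ij} + d^{(i)}(x + e_j) - d^{(i)}(x),}
#' where e_j is the grid unit vector along axis j.  Where x + e_j falls
#' outside the grid the neighboring value is replicated, so the forward
#' difference is zero there (off-diagonal entries 0, diagonal entries 1 along
#' the replicated axis).  The approximation is exact for affine fields.
#'
#' @param field a [displacement_field()].
#' @return An object of class `jacobian_field`: the domain plus nine arrays
#'   `J11`, `J12`, ..., `J33`.
#' @export
forward_jacobian <- function(field) {
  stopifnot(inherits(field, "displacement_field"))
  out <- list(domain = field$domain)
  for (i in 1:3) {
    di <- field_component(field, i)
    for (j in 1:3) {
      entry <- shift_forward(di, j) - di
      if (i == j) entry <- entry + 1
      out[[paste0("J", i, j)]] <- entry
    }
  }
  structure(out, class = "jacobian_field")
}

jac_entry <- function(jac, i, j) jac[[paste0("J", i, j)]]

# Vectorized 3x3 determinant from the nine entry arrays/vectors.
det3 <- function(a11, a12, a13, a21, a22, a23, a31, a32, a33) {
  a11 * (a22 * a33 - a23 * a32) -
    a12 * (a21 * a33 - a23 * a31) +
    a13 * (a21 * a32 - a22 * a31)
}

# Vectorized classical adjugate (transpose of the cofactor matrix); returns
# the nine adjugate entries as a named list, same shapes as the inputs.
adjugate3 <- function(a11, a12, a13, a21, a22, a23, a31, a32, a33) {
  list(
    A11 = a22 * a33 - a23 * a32, A12 = a13 * a32 - a12 * a33,
    A13 = a12 * a23 - a13 * a22,
    A21 = a23 * a31 - a21 * a33, A22 = a11 * a33 - a13 * a31,
    A23 = a13 * a21 - a11 * a23,
    A31 = a21 * a32 - a22 * a31, A32 = a12 * a31 - a11 * a32,
    A33 = a11 * a22 - a12 * a21
  )
}

#' Jacobian determinant image
#'
#' Per-voxel determinant of a forward-difference Jacobian field: the local
#' volume magnification factor of the transformation.  Voxels outside the
#' requested subset are set to `NA`.
#'
#' @param jac a `jacobian_field` from [forward_jacobian()].
#' @param subset optional logical array (the domain's shape) selecting the
#'   voxels to evaluate; `NULL` evaluates everywhere.
#' @return A [scalar_image()] of determinant values.
#' @export
jacobian_determinant <- function(jac, subset = NULL) {
  stopifnot(inherits(jac, "jacobian_field"))
  v <- det3(jac$J11, jac$J12, jac$J13,
            jac$J21, jac$J22, jac$J23,
            jac$J31, jac$J32, jac$J33)
  if (!is.null(subset)) {
    if (!identical(dim(subset), jac$domain$shape))
      stop("'subset' has wrong shape")
    v[!subset] <- NA_real_
  }
  scalar_image(jac$domain, v)
}

#' Ventilation (specific volume change) image
#'
#' The transformation-based CT ventilation metric: the Jacobian determinant
#' minus one, i.e. the estimated fractional volume change of each voxel
#' under phi(x) = x + d(x).  A value of 0 means no volume change; a value of
#' 1 means a 100 percent volume increase.
#'
#' @param field a [displacement_field()].
#' @param subset optional logical array restricting evaluation.
#' @return A [scalar_image()] of ventilation values.
#' @export
ventilation_image <- function(field, subset = NULL) {
  det_img <- jacobian_determinant(forward_jacobian(field), subset)
  scalar_image(field$domain, det_img$values - 1)
}

#' Forward-difference gradient of one displacement component at a voxel
#'
#' Returns the three forward differences of component `component` at voxel
#' `voxel` (1-based index triple), with boundary replication: the discrete
#' gradient used by the perturbation bound.
#'
#' @param field a [displacement_field()].
#' @param component which component (1, 2, or 3).
#' @param voxel integer vector of length 3, 1-based voxel index.
#' @return Numeric 3-vector of forward differences (voxel units).
#' @export
displacement_gradient <- function(field, component, voxel) {
  stopifnot(inherits(field, "displacement_field"))
  n <- field$domain$shape
  voxel <- as.integer(voxel)
  if (length(voxel) != 3L || any(voxel < 1L) || any(voxel > n))
    stop("'voxel' is outside the grid")
  d <- field_component(field, component)
  here <- d[voxel[1], voxel[2], voxel[3]]
  g <- numeric(3)
  for (j in 1:3) {
    nb <- voxel
    if (nb[j] < n[j]) {
      nb[j] <- nb[j] + 1L
      g[j] <- d[nb[1], nb[2], nb[3]] - here
    }  # else replicated neighbor: difference 0
  }
  g
}

# 3x3 Jacobian matrix at a single voxel (1-based index triple).
jacobian_at_voxel <- function(field, voxel) {
  n <- field$domain$shape
  J <- diag(3)
  for (i in 1:3) {
    gi <- displacement_gradient(field, i, voxel)
    J[i, ] <- J[i, ] + gi
  }
  J
}
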