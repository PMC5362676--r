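#' Regular 3D voxel grid domain
#'
#' A `grid_domain` describes the regular voxel lattice on which displacement
#' fields and scalar images live: integer extents along the three axes, the
#' physical voxel spacing in millimeters, and an optional logical mask
#' selecting the region of interest (e.g. the lungs).  All displacement
#' arithmetic in this package is carried out in voxel units; spacing enters
#' only when distances are reported in millimeters.
#'
#' @param shape integer vector of length 3, the number of voxels along each
#'   axis; every extent must be at least 2 so forward differences exist.
#' @param spacing numeric vector of length 3, millimeters per voxel along
#'   each axis (default `c(1, 1, 1)`).
#' @param mask optional logical array of dimension `shape`; `TRUE` marks
#'   voxels inside the region of interest. `NULL` means the whole grid.
#' @return An object of class `grid_domain`.
#' @export
grid_domain <- function(shape, spacing = c(1, 1, 1), mask = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(!is.finite(shape)) || any(shape < 2L))
    stop("'shape' must be three integer extents, each >= 2")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be three positive lengths (mm per voxel)")
  if (!is.null(mask)) {
    if (!is.logical(mask) || !identical(dim(mask), shape))
      stop("'mask' must be a logical array with dim equal to 'shape'")
    if (!any(mask)) stop("'mask' must contain at least one TRUE voxel")
  }
  structure(list(shape = shape, spacing = spacing, mask = mask),
            class = "grid_domain")
}

#' @export
print.grid_domain <- function(x, ...) {
  cat(sprintf("grid_domain: %d x %d x %d voxels, spacing (%g, %g, %g) mm%s\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              if (is.null(x$mask)) "" else
                sprintf(", mask (%d voxels)", sum(x$mask))))
  invisible(x)
}

n_voxels <- function(domain) prod(domain$shape)

#' Logical array marking the region of interest
#'
#' Returns the domain mask, or an all-`TRUE` array when no mask was set.
#'
#' @param domain a [grid_domain()].
#' @return logical array of the domain's shape.
#' @export
domain_mask <- function(domain) {
  if (is.null(domain$mask)) array(TRUE, dim = domain$shape) else domain$mask
}

#' Displacement field on a voxel grid
#'
#' A 3-component vector field d(x) on a regular grid, stored as three scalar
#' volumes.  Component j holds the displacement along axis j measured in
#' voxel units (multiples of the axis-j spacing).  The spatial transformation
#' it defines is phi(x) = x + d(x).
#'
#' @param domain a [grid_domain()].
#' @param d1,d2,d3 numeric arrays of the domain's shape: displacement along
#'   axes 1, 2, 3 in voxel units.
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(domain, d1, d2, d3) {
  stopifnot(inherits(domain, "grid_domain"))
  comps <- list(d1, d2, d3)
  for (j in 1:3) {
    if (!identical(dim(comps[[j]]), domain$shape))
      stop(sprintf("component %d has wrong shape", j))
    if (!all(is.finite(comps[[j]])))
      stop(sprintf("component %d contains non-finite values", j))
  }
  structure(list(domain = domain, d1 = comps[[1]], d2 = comps[[2]],
                 d3 = comps[[3]]),
            class = "displacement_field")
}

#' All-zero displacement field (the identity transformation)
#'
#' @param domain a [grid_domain()].
#' @return A [displacement_field()] with every component zero.
#' @export
zero_field <- function(domain) {
  z <- array(0, dim = domain$shape)
  displacement_field(domain, z, z, z)
}

#' @export
print.displacement_field <- function(x, ...) {
  cat(sprintf("displacement_field on %d x %d x %d grid (voxel units)\n",
              x$domain$shape[1], x$domain$shape[2], x$domain$shape[3]))
  invisible(x)
}

field_component <- function(field, j) {
  switch(j, field$d1, field$d2, field$d3)
}

#' Scalar image on a voxel grid
#'
#' Container for a single scalar volume sharing a [grid_domain()]: Jacobian
#' determinant images, ventilation images, constraint target images f(x),
#' functional images g(x), and masks all use this type.
#'
#' @param domain a [grid_domain()].
#' @param values numeric array of the domain's shape. `NA` is allowed (it
#'   marks voxels outside a requested subset); infinite values are not.
#' @return An object of class `scalar_image`.
#' @export
scalar_image <- function(domain, values) {
  stopifnot(inherits(domain, "grid_domain"))
  if (!identical(dim(values), domain$shape))
    stop("'values' has wrong shape for the domain")
  if (any(is.infinite(values)))
    stop("'values' contains infinite entries")
  structure(list(domain = domain, values = values), class = "scalar_image")
}

#' @export
print.scalar_image <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("scalar_image on %d x %d x %d grid: min %.4g, mean %.4g, max %.4g\n",
              x$domain$shape[1], x$domain$shape[2], x$domain$shape[3],
              min(v), mean(v), max(v)))
  invisible(x)
}

# Voxel coordinate arrays (0-based) for each axis, shaped like the grid.
coordinate_arrays <- function(domain) {
  n <- domain$shape
  list(
    x1 = array(rep.int(0:(n[1] - 1L), n[2] * n[3]), dim = n),
    x2 = array(rep(rep(0:(n[2] - 1L), each = n[1]), n[3]), dim = n),
    x3 = array(rep(0:(n[3] - 1L), each = n[1] * n[2]), dim = n)
  )
}

# Shift an array one voxel backwards along `axis` so that
# out[x] = a[x + e_axis], replicating the far boundary (out = a there).
shift_forward <- function(a, axis) {
  n <- dim(a)
  idx <- lapply(n, seq_len)
  idx[[axis]] <- c(2:n[axis], n[axis])
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

# Linear (1-based, column-major) index of voxel (i1,i2,i3), itself 1-based.
linear_index <- function(shape, i1, i2, i3) {
  i1 + shape[1] * (i2 - 1L) + shape[1] * shape[2] * (i3 - 1L)
}
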