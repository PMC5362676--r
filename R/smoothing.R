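#' Mask-renormalized Gaussian smoothing of a scalar image
#'
#' Convolves the image with a truncated, normalized Gaussian kernel
#' (separable, truncated at 4 sigma).  Smoothing is mask-renormalized:
#' voxels outside the region of interest (and outside the grid) carry zero
#' weight and the kernel is renormalized over the remaining weight, so a
#' constant image stays constant within the mask and output values are
#' convex combinations of input values.  `sigma = 0` returns the input
#' unchanged.
#'
#' @param image a [scalar_image()].
#' @param sigma Gaussian standard deviation in voxels (same along all axes),
#'   must be >= 0.
#' @param mask optional logical array overriding the domain mask.
#' @return A [scalar_image()]; voxels outside the mask are `NA`.
#' @export
gaussian_smooth <- function(image, sigma, mask = NULL) {
  stopifnot(inherits(image, "scalar_image"))
  if (!is.finite(sigma) || sigma < 0)
    stop("'sigma' must be a nonnegative number of voxels")
  if (is.null(mask)) mask <- domain_mask(image$domain)
  if (sigma == 0) {
    v <- image$values
    v[!mask] <- NA_real_
    return(scalar_image(image$domain, v))
  }
  k <- gaussian_kernel_1d(sigma)
  w <- array(as.numeric(mask), dim = image$domain$shape)
  v <- image$values
  v[!mask] <- 0
  num <- convolve_separable(v, k)
  den <- convolve_separable(w, k)
  out <- array(NA_real_, dim = image$domain$shape)
  out[mask] <- num[mask] / den[mask]
  scalar_image(image$domain, out)
}

# Normalized 1D Gaussian taps truncated at 4*sigma.
gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  x <- seq(-r, r)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable 3D convolution with zero padding outside the grid.
convolve_separable <- function(a, k) {
  for (axis in 1:3) a <- convolve_axis(a, k, axis)
  a
}

convolve_axis <- function(a, k, axis) {
  n <- dim(a)
  r <- (length(k) - 1L) %/% 2L
  out <- array(0, dim = n)
  for (t in seq_along(k)) {
    off <- t - r - 1L     # kernel offset in [-r, r]
    src <- seq_len(n[axis]) + off
    keep <- src >= 1L & src <= n[axis]
    if (!any(keep)) next
    idx_out <- lapply(n, seq_len); idx_out[[axis]] <- which(keep)
    idx_in <- idx_out;             idx_in[[axis]] <- src[keep]
    slab <- do.call(`[`, c(list(a), idx_in, list(drop = FALSE)))
    out <- do.call(`[<-`, c(list(out), idx_out,
                            list(do.call(`[`, c(list(out), idx_out,
                                                list(drop = FALSE))) +
                                   k[t] * slab)))
  }
  out
}
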