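#' Write a scalar image to NIfTI
#'
#' Values are stored as 32-bit float with the domain spacing in the header
#' pixdim.  `NA` voxels are written as NaN.
#'
#' @param image a [scalar_image()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_scalar_image <- function(image, path) {
  stopifnot(inherits(image, "scalar_image"))
  img <- RNifti::asNifti(image$values)
  RNifti::pixdim(img) <- image$domain$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a scalar image from NIfTI
#'
#' @param path input path.
#' @param domain optional [grid_domain()] to validate shape against;
#'   when omitted, a domain is built from the header (shape + pixdim).
#' @return A [scalar_image()].
#' @export
read_scalar_image <- function(path, domain = NULL) {
  img <- RNifti::readNifti(path)
  a <- array(as.numeric(img), dim = dim(img))
  if (length(dim(a)) != 3L) stop("expected a 3D scalar volume")
  if (is.null(domain)) {
    domain <- grid_domain(dim(a), spacing = RNifti::pixdim(img)[1:3])
  } else if (!identical(domain$shape, as.integer(dim(a)))) {
    stop("image shape does not match the provided domain")
  }
  scalar_image(domain, a)
}

#' Write a displacement field to NIfTI
#'
#' The three components are stored along the fifth dimension
#' (n1 x n2 x n3 x 1 x 3, the NIfTI vector-volume convention).  With
#' `units = "voxel"` (the internal convention) values are written as-is;
#' with `units = "mm"` each component is multiplied by its axis spacing
#' before writing.
#'
#' @param field a [displacement_field()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @param units `"voxel"` or `"mm"`.
#' @return The path, invisibly.
#' @export
write_vector_field <- function(field, path, units = c("voxel", "mm")) {
  stopifnot(inherits(field, "displacement_field"))
  units <- match.arg(units)
  n <- field$domain$shape
  sp <- field$domain$spacing
  a <- array(0, dim = c(n, 1L, 3L))
  for (j in 1:3) {
    v <- field_component(field, j)
    if (units == "mm") v <- v * sp[j]
    a[, , , 1L, j] <- v
  }
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- c(sp, 1, 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a displacement field from NIfTI
#'
#' Accepts 4D (n1 x n2 x n3 x 3) or 5D (n1 x n2 x n3 x 1 x 3) volumes.
#' `units` declares how the stored values are expressed: `"voxel"` reads
#' them as-is, `"mm"` divides each component by the axis spacing (taken
#' from the header, or from `spacing` when given).
#'
#' @param path input path.
#' @param units `"voxel"` or `"mm"`.
#' @param spacing optional numeric 3-vector overriding the header pixdim.
#' @return A [displacement_field()].
#' @export
read_vector_field <- function(path, units = c("voxel", "mm"),
                              spacing = NULL) {
  units <- match.arg(units)
  img <- RNifti::readNifti(path)
  a <- array(as.numeric(img), dim = dim(img))
  dm <- dim(a)
  if (length(dm) == 5L && dm[4] == 1L && dm[5] == 3L) {
    comps <- lapply(1:3, function(j) a[, , , 1L, j])
  } else if (length(dm) == 4L && dm[4] == 3L) {
    comps <- lapply(1:3, function(j) a[, , , j])
  } else {
    stop(sprintf("expected a 3-component vector volume, got dims [%s]",
                 paste(dm, collapse = ", ")))
  }
  sp <- if (is.null(spacing)) RNifti::pixdim(img)[1:3] else as.numeric(spacing)
  if (units == "mm" && (any(!is.finite(sp)) || any(sp <= 0)))
    stop("mm-unit field requires positive voxel spacing metadata")
  domain <- grid_domain(dm[1:3], spacing = sp)
  if (units == "mm") comps <- lapply(1:3, function(j) comps[[j]] / sp[j])
  displacement_field(domain, comps[[1]], comps[[2]], comps[[3]])
}

#' Write fidelity data as CSV
#'
#' Columns `i1,i2,i3` (1-based voxel indices) and `y1,y2,y3` (voxel-unit
#' displacement estimates).
#'
#' @param fidelity a [fidelity_data()].
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_fidelity_csv <- function(fidelity, path) {
  stopifnot(inherits(fidelity, "fidelity_data"))
  df <- data.frame(i1 = fidelity$indices[, 1], i2 = fidelity$indices[, 2],
                   i3 = fidelity$indices[, 3], y1 = fidelity$values[, 1],
                   y2 = fidelity$values[, 2], y3 = fidelity$values[, 3])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read fidelity data from CSV
#'
#' @param path CSV with columns `i1,i2,i3,y1,y2,y3`.
#' @param domain a [grid_domain()].
#' @return A [fidelity_data()].
#' @export
read_fidelity_csv <- function(path, domain) {
  df <- utils::read.csv(path)
  need <- c("i1", "i2", "i3", "y1", "y2", "y3")
  if (!all(need %in% names(df)))
    stop("fidelity CSV must have columns i1,i2,i3,y1,y2,y3")
  fidelity_data(domain, as.matrix(df[, c("i1", "i2", "i3")]),
                as.matrix(df[, c("y1", "y2", "y3")]))
}

#' Write landmark points as whitespace-delimited text
#'
#' @param points numeric matrix, n x 3, of 0-based points.
#' @param path output path.
#' @param index_base 0 or 1 (default 1, the dir-lab convention).
#' @return The path, invisibly.
#' @export
write_landmarks <- function(points, path, index_base = 1) {
  points <- matrix(as.numeric(points), ncol = 3) + index_base
  writeLines(apply(points, 1, function(r) paste(format(r, trim = TRUE),
                                                collapse = " ")), path)
  invisible(path)
}
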