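#' Paired landmark set for spatial-accuracy evaluation
#'
#' Expert-annotated corresponding points in the reference and target image
#' phases, in continuous voxel coordinates (internally 0-based), plus the
#' physical voxel spacing used to report errors in millimeters.
#'
#' @param reference numeric matrix, n x 3, reference-phase points (0-based
#'   voxel coordinates).
#' @param target numeric matrix, n x 3, corresponding target-phase points.
#' @param spacing numeric 3-vector, mm per voxel.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(reference, target, spacing = c(1, 1, 1)) {
  reference <- matrix(as.numeric(reference), ncol = 3)
  target <- matrix(as.numeric(target), ncol = 3)
  if (nrow(reference) < 1L || nrow(reference) != nrow(target))
    stop("reference/target must be equally long, with at least one pair")
  if (any(!is.finite(reference)) || any(!is.finite(target)))
    stop("landmark coordinates must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("'spacing' must be three positive lengths")
  structure(list(reference = reference, target = target, spacing = spacing),
            class = "landmark_set")
}

#' Read landmark points from a whitespace-delimited text file
#'
#' Each row holds three numbers (the dir-lab convention).  `index_base`
#' declares whether the stored coordinates are 1-based (dir-lab default)
#' or 0-based; points are converted to the package's 0-based internal
#' convention on read.
#'
#' @param path text file path.
#' @param index_base 0 or 1 (default 1, the dir-lab convention).
#' @return numeric matrix, n x 3, of 0-based points.
#' @export
read_landmarks <- function(path, index_base = 1) {
  if (!index_base %in% c(0, 1)) stop("'index_base' must be 0 or 1")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop(sprintf("no landmark rows in '%s'", path))
  pts <- matrix(NA_real_, nrow = length(lines), ncol = 3)
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    val <- suppressWarnings(as.numeric(tok))
    if (length(val) != 3L || any(!is.finite(val)))
      stop(sprintf("malformed landmark row at line %d of '%s': '%s'",
                   i, path, lines[i]))
    pts[i, ] <- val
  }
  pts - index_base
}

#' Map points through a displacement field
#'
#' Applies the transformation phi(x) = x + d(x) to continuous points, with
#' d interpolated trilinearly; points lying exactly on grid nodes use the
#' stored vector exactly.  Points are 0-based voxel coordinates; the result
#' is in the same units.
#'
#' @param field a [displacement_field()].
#' @param points numeric matrix, n x 3, of 0-based points inside the grid.
#' @return numeric matrix, n x 3, of mapped points.
#' @export
map_points <- function(field, points) {
  stopifnot(inherits(field, "displacement_field"))
  points <- matrix(as.numeric(points), ncol = 3)
  n <- field$domain$shape
  if (any(points < 0) || any(points[, 1] > n[1] - 1) ||
      any(points[, 2] > n[2] - 1) || any(points[, 3] > n[3] - 1))
    stop("point(s) outside the grid")
  d <- vapply(1:3, function(j) trilinear(field_component(field, j), points),
              numeric(nrow(points)))
  points + d
}

# Trilinear interpolation of array `a` at 0-based continuous points (n x 3).
trilinear <- function(a, points) {
  n <- dim(a)
  i0 <- pmin(floor(points), rep(n - 2L, each = nrow(points))) # corner, 0-based
  i0 <- pmax(i0, 0)
  t <- points - i0
  out <- numeric(nrow(points))
  for (c1 in 0:1) for (c2 in 0:1) for (c3 in 0:1) {
    w <- (c1 * t[, 1] + (1 - c1) * (1 - t[, 1])) *
      (c2 * t[, 2] + (1 - c2) * (1 - t[, 2])) *
      (c3 * t[, 3] + (1 - c3) * (1 - t[, 3]))
    lin <- linear_index(n, i0[, 1] + c1 + 1L, i0[, 2] + c2 + 1L,
                        i0[, 3] + c3 + 1L)
    out <- out + w * a[lin]
  }
  out
}

#' Landmark spatial-accuracy statistics in millimeters
#'
#' Maps each reference landmark through the field and measures the
#' Euclidean distance in millimeters to the corresponding target landmark:
#' per-landmark error = || (phi(reference) - target) * spacing ||_2.
#' This is the target registration error (TRE) protocol used to validate
#' deformable registrations against expert point pairs.
#'
#' @param field a [displacement_field()].
#' @param landmarks a [landmark_set()].
#' @param std which standard deviation to report: `"population"` (divide
#'   by n, the default) or `"sample"` (divide by n - 1).
#' @return A list: `mean_mm`, `std_mm`, `max_mm`, `n`, and `per_landmark`
#'   (data frame with mapped coordinates and mm error per pair).
#' @export
landmark_error_stats <- function(field, landmarks, std = c("population",
                                                           "sample")) {
  stopifnot(inherits(landmarks, "landmark_set"))
  std <- match.arg(std)
  mapped <- map_points(field, landmarks$reference)
  diff_mm <- sweep(mapped - landmarks$target, 2, landmarks$spacing, `*`)
  err <- sqrt(rowSums(diff_mm^2))
  nlm <- length(err)
  sd_val <- if (std == "population") sqrt(mean((err - mean(err))^2))
            else stats::sd(err)
  list(mean_mm = mean(err), std_mm = sd_val, max_mm = max(err), n = nlm,
       per_landmark = data.frame(
         ref1 = landmarks$reference[, 1], ref2 = landmarks$reference[, 2],
         ref3 = landmarks$reference[, 3],
         mapped1 = mapped[, 1], mapped2 = mapped[, 2], mapped3 = mapped[, 3],
         error_mm = err))
}
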