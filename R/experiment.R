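#' Pearson correlation between two scalar images over a mask
#'
#' @param a,b [scalar_image()]s on the same domain.
#' @param mask optional logical array; defaults to voxels where both images
#'   are non-`NA` within the domain mask.
#' @return Scalar Pearson correlation.
#' @export
image_correlation <- function(a, b, mask = NULL) {
  stopifnot(inherits(a, "scalar_image"), inherits(b, "scalar_image"))
  if (is.null(mask)) mask <- domain_mask(a$domain)
  mask <- mask & !is.na(a$values) & !is.na(b$values)
  stats::cor(a$values[mask], b$values[mask])
}

#' Run a full constrained-ventilation experiment
#'
#' End-to-end driver mirroring the study protocol: fit the unconstrained
#' field from fidelity data, build a target Jacobian image in one of three
#' modes, solve the Jacobian-constrained problem, and report ventilation
#' statistics, constraint violation, landmark accuracy (when landmarks are
#' given), histogram data for the Jacobian distributions, and, in
#' correlation mode, the Jacobian-functional scatter data.
#'
#' Constraint modes:
#' \describe{
#'   \item{`smooth`}{f = Gaussian-smoothed unconstrained Jacobian
#'     (`sigma`).}
#'   \item{`bounds`}{f = smoothed clip of the unconstrained Jacobian to
#'     `[LB, UB]` (contraction/expansion).}
#'   \item{`correlation`}{f = a* g + b* with (a*, b*) the least-squares
#'     fit of the unconstrained Jacobian on the functional image `g`.}
#'   \item{`identity`}{f = the unconstrained Jacobian itself (the solve
#'     starts feasible; a consistency check).}
#' }
#'
#' @param fidelity a [fidelity_data()].
#' @param constraint a list with `mode` plus mode parameters: `sigma`
#'   (smooth/bounds), `LB`, `UB` (bounds), `g` a [scalar_image()]
#'   (correlation).
#' @param opts a [solver_options()].
#' @param landmarks optional [landmark_set()] for accuracy evaluation.
#' @param out_dir optional directory: writes the solution field, Jacobian
#'   and ventilation images (NIfTI), histogram/scatter CSVs and the JSON
#'   report there.
#' @param hist_breaks number of histogram bins (default 50).
#' @return A list of class `experiment_report`; see Details for fields.
#' @export
run_experiment <- function(fidelity, constraint, opts = solver_options(),
                           landmarks = NULL, out_dir = NULL,
                           hist_breaks = 50L) {
  stopifnot(inherits(fidelity, "fidelity_data"))
  if (is.null(constraint$mode)) stop("constraint$mode is required")
  domain <- fidelity$domain
  constrained <- constrained_voxel_set(domain)

  unc <- fit_unconstrained(fidelity, opts$alpha, domain)
  unc_jac <- jacobian_determinant(forward_jacobian(unc))

  f <- switch(constraint$mode,
    smooth = smoothed_constraint(unc_jac, constraint$sigma),
    bounds = bound_constraint(unc_jac,
                              bound_spec(constraint$LB, constraint$UB,
                                         constraint$sigma %||% 1)),
    correlation = {
      map <- fit_linear_map(constraint$g, unc_jac, mask = constrained)
      correlation_constraint(constraint$g, map, mask = constrained)
    },
    identity = unc_jac,
    stop(sprintf("unknown constraint mode '%s'", constraint$mode)))

  sol <- solve_constrained(fidelity, f, opts, init = unc)
  con_jac <- jacobian_determinant(forward_jacobian(sol$field))
  vent <- scalar_image(domain, con_jac$values - 1)

  jac_stats <- function(img) {
    v <- img$values[constrained]
    list(mean = mean(v), sd = stats::sd(v), min = min(v), max = max(v))
  }
  rng <- range(unc_jac$values[constrained], con_jac$values[constrained])
  brk <- seq(rng[1] - 1e-9, rng[2] + 1e-9, length.out = hist_breaks + 1L)
  hist_df <- data.frame(
    bin_low = brk[-length(brk)], bin_high = brk[-1],
    unconstrained = as.integer(table(cut(unc_jac$values[constrained], brk))),
    constrained = as.integer(table(cut(con_jac$values[constrained], brk))))

  report <- list(
    constraint = constraint[setdiff(names(constraint), "g")],
    options = unclass(opts),
    unconstrained_jacobian = jac_stats(unc_jac),
    constrained_jacobian = jac_stats(con_jac),
    max_violation = sol$state$max_violation,
    converged = sol$state$converged,
    outer_iterations = sol$state$outer_iterations,
    min_det = sol$state$min_det,
    histogram = hist_df,
    package_version = as.character(utils::packageVersion("ventjac")))

  if (identical(constraint$mode, "correlation")) {
    report$correlation_unconstrained <-
      image_correlation(unc_jac, constraint$g, mask = constrained)
    report$correlation_constrained <-
      image_correlation(con_jac, constraint$g, mask = constrained)
    report$scatter <- data.frame(
      g = constraint$g$values[constrained],
      jac_unconstrained = unc_jac$values[constrained],
      jac_constrained = con_jac$values[constrained])
  }
  if (!is.null(landmarks)) {
    report$accuracy_unconstrained <-
      landmark_error_stats(unc, landmarks)[c("mean_mm", "std_mm", "max_mm")]
    report$accuracy_constrained <-
      landmark_error_stats(sol$field, landmarks)[c("mean_mm", "std_mm",
                                                   "max_mm")]
  }

  result <- structure(list(report = report, field = sol$field,
                           unconstrained_field = unc, target = f,
                           jacobian = con_jac, ventilation = vent,
                           state = sol$state),
                      class = "experiment_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_vector_field(sol$field, file.path(out_dir, "field.nii.gz"))
    write_scalar_image(con_jac, file.path(out_dir, "jacobian.nii.gz"))
    write_scalar_image(vent, file.path(out_dir, "ventilation.nii.gz"))
    utils::write.csv(hist_df, file.path(out_dir, "histogram.csv"),
                     row.names = FALSE)
    if (!is.null(report$scatter))
      utils::write.csv(report$scatter, file.path(out_dir, "scatter.csv"),
                       row.names = FALSE)
    json <- report
    json$histogram <- NULL; json$scatter <- NULL
    jsonlite::write_json(json, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}

#' @export
print.experiment_report <- function(x, ...) {
  r <- x$report
  cat(sprintf("experiment (%s constraint): %s\n", r$constraint$mode,
              if (r$converged) "converged" else "NOT converged"))
  cat(sprintf("  Jacobian mean (sd): unconstrained %.2f (%.2f) -> constrained %.2f (%.2f)\n",
              r$unconstrained_jacobian$mean, r$unconstrained_jacobian$sd,
              r$constrained_jacobian$mean, r$constrained_jacobian$sd))
  cat(sprintf("  max |det - f| = %.2e\n", r$max_violation))
  if (!is.null(r$correlation_constrained))
    cat(sprintf("  correlation with g: %.2f -> %.2f\n",
                r$correlation_unconstrained, r$correlation_constrained))
  if (!is.null(r$accuracy_constrained))
    cat(sprintf("  landmark error (mm): %.2f (%.2f) -> %.2f (%.2f)\n",
                r$accuracy_unconstrained$mean_mm,
                r$accuracy_unconstrained$std_mm,
                r$accuracy_constrained$mean_mm,
                r$accuracy_constrained$std_mm))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
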