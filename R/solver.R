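#' A priori displacement estimates (fidelity data)
#'
#' Displacement estimates y_i at a subset of voxel locations, typically
#' produced by an upstream deformable-registration algorithm.  The
#' constrained solver anchors its solution to these values.
#'
#' @param domain a [grid_domain()].
#' @param indices integer matrix, M x 3, of 1-based voxel index triples;
#'   rows must be unique and inside the grid.
#' @param values numeric matrix, M x 3, of displacement estimates in voxel
#'   units (column j = component j).
#' @return An object of class `fidelity_data`.
#' @export
fidelity_data <- function(domain, indices, values) {
  stopifnot(inherits(domain, "grid_domain"))
  indices <- matrix(as.integer(indices), ncol = 3)
  values <- matrix(as.numeric(values), ncol = 3)
  if (nrow(indices) < 1L) stop("fidelity data must contain at least one voxel")
  if (nrow(indices) != nrow(values)) stop("indices/values row mismatch")
  n <- domain$shape
  if (any(indices < 1L) || any(indices[, 1] > n[1]) ||
      any(indices[, 2] > n[2]) || any(indices[, 3] > n[3]))
    stop("fidelity indices outside the grid")
  lin <- linear_index(n, indices[, 1], indices[, 2], indices[, 3])
  if (anyDuplicated(lin)) stop("fidelity indices must be unique")
  if (any(!is.finite(values))) stop("fidelity values must be finite")
  structure(list(domain = domain, indices = indices, values = values,
                 linear = lin),
            class = "fidelity_data")
}

#' @export
print.fidelity_data <- function(x, ...) {
  cat(sprintf("fidelity_data: %d voxels with displacement estimates\n",
              nrow(x$indices)))
  invisible(x)
}

#' Solver options for the augmented Lagrangian method
#'
#' @param alpha Laplacian regularization weight (>= 0); larger values give
#'   smoother fields that track the fidelity data less closely.
#' @param constraint_tol convergence tolerance on the maximum absolute
#'   Jacobian constraint violation (default 1e-3).
#' @param mu0 initial quadratic-penalty parameter.
#' @param growth penalty growth factor (> 1), applied when the violation
#'   does not shrink fast enough.
#' @param shrink_ratio required per-iteration violation shrink factor; if
#'   `max|c|` does not fall below `shrink_ratio` times the previous value,
#'   the penalty grows.
#' @param max_outer maximum number of outer (multiplier) iterations.
#' @param inner_maxit L-BFGS iteration cap per inner solve.
#' @param inner_pgtol0 initial projected-gradient tolerance of the inner
#'   solve; tightened geometrically each outer iteration.
#' @param inner_pgtol_shrink geometric tightening factor per outer iteration.
#' @param inner_pgtol_min floor for the inner tolerance.
#' @return An object of class `solver_options`.
#' @export
solver_options <- function(alpha = 1, constraint_tol = 1e-3, mu0 = 10,
                           growth = 10, shrink_ratio = 0.25, max_outer = 20L,
                           inner_maxit = 2000L, inner_pgtol0 = 1e-2,
                           inner_pgtol_shrink = 0.1, inner_pgtol_min = 1e-8) {
  if (alpha < 0) stop("'alpha' must be >= 0")
  if (constraint_tol <= 0 || mu0 <= 0 || inner_pgtol0 <= 0)
    stop("tolerances and penalties must be > 0")
  if (growth <= 1) stop("'growth' must be > 1")
  structure(list(alpha = alpha, constraint_tol = constraint_tol, mu0 = mu0,
                 growth = growth, shrink_ratio = shrink_ratio,
                 max_outer = as.integer(max_outer),
                 inner_maxit = as.integer(inner_maxit),
                 inner_pgtol0 = inner_pgtol0,
                 inner_pgtol_shrink = inner_pgtol_shrink,
                 inner_pgtol_min = inner_pgtol_min),
            class = "solver_options")
}

#' Laplacian-regularized least-squares displacement field fit
#'
#' Solves, independently for each displacement component,
#' \deqn{\min_d \sum_{i \in I} \|d(x_i) - y_i\|^2
#'       + \alpha \sum_j \|A \tilde d_j\|^2,}
#' where A is the Neumann 7-point Laplacian.  With `alpha > 0` the problem
#' is strictly convex and has a unique minimizer (solved by sparse
#' Cholesky).  With `alpha = 0` the fidelity data must cover every voxel,
#' in which case the fit returns the data exactly.
#'
#' @param fidelity a [fidelity_data()].
#' @param alpha regularization weight, >= 0.
#' @param domain optional [grid_domain()] (defaults to the fidelity domain).
#' @return A [displacement_field()].
#' @export
fit_unconstrained <- function(fidelity, alpha = 1, domain = NULL) {
  stopifnot(inherits(fidelity, "fidelity_data"))
  if (is.null(domain)) domain <- fidelity$domain
  N <- n_voxels(domain)
  if (alpha < 0) stop("'alpha' must be >= 0")
  if (alpha == 0) {
    if (nrow(fidelity$indices) < N)
      stop("alpha = 0 requires fidelity data at every voxel (ill-posed)")
    comps <- lapply(1:3, function(j) {
      v <- numeric(N); v[fidelity$linear] <- fidelity$values[, j]
      array(v, dim = domain$shape)
    })
    return(displacement_field(domain, comps[[1]], comps[[2]], comps[[3]]))
  }
  A <- assemble_laplacian(domain)
  AtA <- Matrix::crossprod(A)
  sel <- numeric(N); sel[fidelity$linear] <- 1
  M <- AtA * alpha + Matrix::Diagonal(N, sel)
  comps <- lapply(1:3, function(j) {
    rhs <- numeric(N); rhs[fidelity$linear] <- fidelity$values[, j]
    array(as.numeric(Matrix::solve(M, rhs)), dim = domain$shape)
  })
  displacement_field(domain, comps[[1]], comps[[2]], comps[[3]])
}

#' Voxels at which the Jacobian equality constraint is enforced
#'
#' Constraints are imposed only where the forward-difference Jacobian is
#' fully defined from grid data: voxels whose three forward neighbors lie
#' inside the grid and (when a mask is present) whose own location and
#' neighbors are inside the mask.
#'
#' @param domain a [grid_domain()].
#' @return logical array of the domain's shape.
#' @export
constrained_voxel_set <- function(domain) {
  n <- domain$shape
  m <- domain_mask(domain)
  ok <- m & shift_forward(m, 1) & shift_forward(m, 2) & shift_forward(m, 3)
  co <- coordinate_arrays(domain)  # 0-based
  ok & (co$x1 < n[1] - 1L) & (co$x2 < n[2] - 1L) & (co$x3 < n[3] - 1L)
}

#' Jacobian constraint residual image
#'
#' c_k = det(J~(x_k; d)) - f(x_k) on the constrained voxel set; `NA`
#' elsewhere.
#'
#' @param field a [displacement_field()].
#' @param f [scalar_image()], the target Jacobian image (strictly positive
#'   on the constrained set).
#' @param constrained optional logical array; defaults to
#'   [constrained_voxel_set()] of the field's domain.
#' @return A [scalar_image()] of residuals.
#' @export
constraint_residual <- function(field, f, constrained = NULL) {
  stopifnot(inherits(field, "displacement_field"), inherits(f, "scalar_image"))
  if (is.null(constrained)) constrained <- constrained_voxel_set(field$domain)
  det_img <- jacobian_determinant(forward_jacobian(field))
  v <- det_img$values - f$values
  v[!constrained] <- NA_real_
  scalar_image(field$domain, v)
}

# ---- internal flat-vector machinery ---------------------------------------

# Precomputed context for the augmented Lagrangian inner problem.
al_context <- function(domain, fidelity, alpha, f, constrained) {
  n <- domain$shape
  N <- prod(n)
  A <- assemble_laplacian(domain)
  ck <- which(constrained)                 # linear indices, axis-1 fastest
  off <- c(1L, n[1], n[1] * n[2])
  fv <- f$values[ck]
  if (any(!is.finite(fv)) || any(fv <= 0))
    stop("target Jacobian image must be finite and > 0 on the constrained set")
  list(n = n, N = N, AtA = Matrix::crossprod(A), alpha = alpha,
       fid_lin = fidelity$linear, y = fidelity$values,
       ck = ck, off = off, fv = fv)
}

# Jacobian entries at constrained voxels from the three flat components.
al_jac_entries <- function(d1, d2, d3, ctx) {
  ck <- ctx$ck; off <- ctx$off
  J <- vector("list", 9L)
  dim(J) <- c(3L, 3L)
  comps <- list(d1, d2, d3)
  for (i in 1:3) for (j in 1:3) {
    e <- comps[[i]][ck + off[j]] - comps[[i]][ck]
    if (i == j) e <- e + 1
    J[[i, j]] <- e
  }
  J
}

# Value and gradient of the augmented Lagrangian at flat x = c(d1, d2, d3).
al_value_grad <- function(x, ctx, lambda, mu) {
  N <- ctx$N
  d1 <- x[1:N]; d2 <- x[(N + 1):(2 * N)]; d3 <- x[(2 * N + 1):(3 * N)]
  comps <- list(d1, d2, d3)
  grad <- list(numeric(N), numeric(N), numeric(N))

  val <- 0
  for (j in 1:3) {
    r <- comps[[j]][ctx$fid_lin] - ctx$y[, j]
    val <- val + sum(r * r)
    grad[[j]][ctx$fid_lin] <- grad[[j]][ctx$fid_lin] + 2 * r
    if (ctx$alpha > 0) {
      Ad <- as.numeric(ctx$AtA %*% comps[[j]])
      val <- val + ctx$alpha * sum(comps[[j]] * Ad)
      grad[[j]] <- grad[[j]] + 2 * ctx$alpha * Ad
    }
  }

  J <- al_jac_entries(d1, d2, d3, ctx)
  detv <- det3(J[[1, 1]], J[[1, 2]], J[[1, 3]],
               J[[2, 1]], J[[2, 2]], J[[2, 3]],
               J[[3, 1]], J[[3, 2]], J[[3, 3]])
  cres <- detv - ctx$fv
  val <- val + sum(lambda * cres) + (mu / 2) * sum(cres * cres)
  w <- lambda + mu * cres

  # cofactors C[i,j] = d det / d J[i,j]
  C <- vector("list", 9L); dim(C) <- c(3L, 3L)
  C[[1, 1]] <- J[[2, 2]] * J[[3, 3]] - J[[2, 3]] * J[[3, 2]]
  C[[1, 2]] <- J[[2, 3]] * J[[3, 1]] - J[[2, 1]] * J[[3, 3]]
  C[[1, 3]] <- J[[2, 1]] * J[[3, 2]] - J[[2, 2]] * J[[3, 1]]
  C[[2, 1]] <- J[[1, 3]] * J[[3, 2]] - J[[1, 2]] * J[[3, 3]]
  C[[2, 2]] <- J[[1, 1]] * J[[3, 3]] - J[[1, 3]] * J[[3, 1]]
  C[[2, 3]] <- J[[1, 2]] * J[[3, 1]] - J[[1, 1]] * J[[3, 2]]
  C[[3, 1]] <- J[[1, 2]] * J[[2, 3]] - J[[1, 3]] * J[[2, 2]]
  C[[3, 2]] <- J[[1, 3]] * J[[2, 1]] - J[[1, 1]] * J[[2, 3]]
  C[[3, 3]] <- J[[1, 1]] * J[[2, 2]] - J[[1, 2]] * J[[2, 1]]

  ck <- ctx$ck; off <- ctx$off
  for (i in 1:3) {
    diag_sum <- numeric(length(ck))
    for (j in 1:3) {
      contrib <- w * C[[i, j]]
      tgt <- ck + off[j]
      grad[[i]][tgt] <- grad[[i]][tgt] + contrib
      diag_sum <- diag_sum + contrib
    }
    grad[[i]][ck] <- grad[[i]][ck] - diag_sum
  }

  list(value = val, grad = c(grad[[1]], grad[[2]], grad[[3]]),
       residual = cres)
}

#' Augmented Lagrangian objective value and analytic gradient
#'
#' Evaluates
#' \deqn{\sum_{i \in I}\|d(x_i)-y_i\|^2 + \alpha\sum_j\|A\tilde d_j\|^2
#'       + \sum_k \lambda_k c_k + \frac{\mu}{2}\sum_k c_k^2,}
#' with c_k the Jacobian constraint residuals, together with its exact
#' gradient with respect to every displacement entry.  The determinant
#' derivative uses the cofactor matrix; each residual's gradient touches
#' the at most 12 displacement entries entering the forward-difference
#' Jacobian at its voxel.  With `mu = 0` and `lambda = 0` this reduces to
#' the unconstrained regularized least-squares objective.
#'
#' @param field a [displacement_field()], the evaluation point.
#' @param fidelity a [fidelity_data()].
#' @param alpha regularization weight.
#' @param f [scalar_image()] target Jacobian image.
#' @param lambda numeric vector of multipliers, one per constrained voxel
#'   (ordering of `which(constrained_voxel_set(domain))`); scalars recycle.
#' @param mu penalty parameter, >= 0.
#' @return A list: `value` (scalar), `gradient` (list of three arrays),
#'   `residual` (vector of c_k over the constrained set).
#' @export
augmented_objective_gradient <- function(field, fidelity, alpha, f,
                                         lambda = 0, mu = 0) {
  stopifnot(inherits(field, "displacement_field"))
  constrained <- constrained_voxel_set(field$domain)
  ctx <- al_context(field$domain, fidelity, alpha, f, constrained)
  lambda <- rep_len(lambda, length(ctx$ck))
  x <- c(as.numeric(field$d1), as.numeric(field$d2), as.numeric(field$d3))
  r <- al_value_grad(x, ctx, lambda, mu)
  N <- ctx$N
  list(value = r$value,
       gradient = list(array(r$grad[1:N], ctx$n),
                       array(r$grad[(N + 1):(2 * N)], ctx$n),
                       array(r$grad[(2 * N + 1):(3 * N)], ctx$n)),
       residual = r$residual)
}

#' Jacobian-constrained displacement field solve
#'
#' Computes a smooth displacement field that agrees with the fidelity data
#' while its forward-difference Jacobian determinant equals a user-defined
#' target image f at every constrained voxel:
#' \deqn{\min_d \sum_{i\in I}\|d(x_i)-y_i\|^2 + \alpha\sum_j\|A\tilde d_j\|^2
#'       \quad \mathrm{s.t.}\quad \det(\tilde J(x_k; d)) = f(x_k).}
#' The nonconvex equality-constrained problem is solved with the classical
#' augmented Lagrangian method: starting from the unconstrained fit
#' ([fit_unconstrained()]), each outer iteration minimizes the augmented
#' Lagrangian with L-BFGS-B using analytic gradients, then updates the
#' multipliers (lambda <- lambda + mu c) and grows the penalty when the
#' maximum violation fails to shrink by `shrink_ratio`.  The inner
#' tolerance tightens geometrically.  The whole procedure is deterministic.
#'
#' @param fidelity a [fidelity_data()].
#' @param f [scalar_image()], the target Jacobian image; must pass
#'   [validate_constraint()] on the constrained set.
#' @param opts a [solver_options()].
#' @param init optional [displacement_field()] initial iterate (defaults to
#'   the unconstrained fit).
#' @param verbose print per-outer-iteration progress.
#' @return A list of class `constrained_solution`: `field` (the solution),
#'   and `state` with `converged`, `max_violation`, `outer_iterations`,
#'   `lambda`, `mu`, `min_det` (minimum Jacobian determinant on the
#'   constrained set, reported so positivity can be audited), and a
#'   per-iteration `history` data frame.  A non-convergent run returns the
#'   best iterate with `converged = FALSE`, never a silent success.
#' @export
solve_constrained <- function(fidelity, f, opts = solver_options(),
                              init = NULL, verbose = FALSE) {
  stopifnot(inherits(fidelity, "fidelity_data"), inherits(f, "scalar_image"),
            inherits(opts, "solver_options"))
  domain <- fidelity$domain
  constrained <- constrained_voxel_set(domain)
  rep_f <- validate_constraint(f, mask = constrained)
  if (!rep_f$ok)
    stop(sprintf("target Jacobian image invalid on the constrained set (%d nonpositive, %d nonfinite voxels)",
                 rep_f$n_nonpositive, rep_f$n_nonfinite))
  ctx <- al_context(domain, fidelity, opts$alpha, f, constrained)

  if (is.null(init)) init <- fit_unconstrained(fidelity, opts$alpha, domain)
  x <- c(as.numeric(init$d1), as.numeric(init$d2), as.numeric(init$d3))

  lambda <- numeric(length(ctx$ck))
  mu <- opts$mu0
  pgtol <- opts$inner_pgtol0
  hist <- data.frame(outer = integer(), objective = double(),
                     max_violation = double(), mu = double(),
                     inner_convergence = integer())
  best_x <- x
  best_viol <- max(abs(al_value_grad(x, ctx, lambda, 0)$residual))
  prev_viol <- best_viol
  converged <- FALSE

  for (outer in seq_len(opts$max_outer)) {
    fit <- stats::optim(
      par = x,
      fn = function(z) al_value_grad(z, ctx, lambda, mu)$value,
      gr = function(z) al_value_grad(z, ctx, lambda, mu)$grad,
      method = "L-BFGS-B",
      control = list(maxit = opts$inner_maxit, pgtol = pgtol, factr = 10))
    x <- fit$par
    ev <- al_value_grad(x, ctx, lambda, mu)
    viol <- max(abs(ev$residual))
    hist <- rbind(hist, data.frame(outer = outer, objective = ev$value,
                                   max_violation = viol, mu = mu,
                                   inner_convergence = fit$convergence))
    if (verbose)
      message(sprintf("outer %2d: objective %.6g, max|c| %.3e, mu %.1e",
                      outer, ev$value, viol, mu))
    if (viol < best_viol) { best_viol <- viol; best_x <- x }
    if (viol <= opts$constraint_tol) { converged <- TRUE; break }
    lambda <- lambda + mu * ev$residual
    if (viol > opts$shrink_ratio * prev_viol) mu <- mu * opts$growth
    prev_viol <- viol
    pgtol <- max(opts$inner_pgtol_min, pgtol * opts$inner_pgtol_shrink)
  }

  if (!converged) x <- best_x
  N <- ctx$N
  field <- displacement_field(domain,
                              array(x[1:N], ctx$n),
                              array(x[(N + 1):(2 * N)], ctx$n),
                              array(x[(2 * N + 1):(3 * N)], ctx$n))
  final_res <- al_value_grad(x, ctx, lambda, 0)$residual
  min_det <- min(final_res + ctx$fv)
  if (!converged)
    warning(sprintf("augmented Lagrangian did not reach constraint_tol %.1e (best max|c| = %.3e); returning best iterate",
                    opts$constraint_tol, best_viol))
  structure(list(
    field = field,
    state = list(converged = converged,
                 max_violation = max(abs(final_res)),
                 outer_iterations = nrow(hist),
                 history = hist, lambda = lambda, mu = mu,
                 min_det = min_det, options = opts)),
    class = "constrained_solution")
}

#' @export
print.constrained_solution <- function(x, ...) {
  s <- x$state
  cat(sprintf("constrained_solution: %s after %d outer iteration(s)\n",
              if (s$converged) "converged" else "NOT converged",
              s$outer_iterations))
  cat(sprintf("  max |det - f| = %.3e, min det = %.4f\n",
              s$max_violation, s$min_det))
  invisible(x)
}
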