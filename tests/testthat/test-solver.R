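test_that("unconstrained fit interpolates full-coverage data at alpha 0", {
  dom <- grid_domain(c(4, 4, 4))
  fld <- smooth_test_field(c(4, 4, 4), seed = 1)
  fid <- sample_fidelity(fld, fraction = 1, noise_sigma = 0, seed = 2)
  fit0 <- fit_unconstrained(fid, alpha = 0)
  expect_equal(fit0$d1, fld$d1, tolerance = 1e-14)
  expect_equal(fit0$d3, fld$d3, tolerance = 1e-14)

  part <- sample_fidelity(fld, fraction = 0.3, noise_sigma = 0, seed = 3)
  expect_error(fit_unconstrained(part, alpha = 0), "ill-posed")
})

test_that("very large alpha drives each component to the mean of its fidelity values", {
  fld <- smooth_test_field(c(6, 6, 6), seed = 4)
  fid <- sample_fidelity(fld, fraction = 0.25, noise_sigma = 0, seed = 5)
  fit <- fit_unconstrained(fid, alpha = 1e8)
  for (j in 1:3) {
    target <- mean(fid$values[, j])
    comp <- ventjac:::field_component(fit, j)
    expect_lt(max(abs(comp - target)), 1e-4)
  }
})

test_that("sparse regularized fit matches the dense normal-equations solve", {
  dom <- grid_domain(c(6, 6, 6))
  fld <- smooth_test_field(c(6, 6, 6), seed = 6)
  fid <- sample_fidelity(fld, fraction = 20 / 216, noise_sigma = 0.1, seed = 7)
  fit <- fit_unconstrained(fid, alpha = 1)

  D <- oracle_dense_laplacian(c(6, 6, 6))
  sel <- rep(0, 216); sel[fid$linear] <- 1
  Mns <- t(D) %*% D + diag(sel)
  for (j in 1:3) {
    rhs <- rep(0, 216); rhs[fid$linear] <- fid$values[, j]
    d_dense <- solve(Mns, rhs)
    comp <- as.numeric(ventjac:::field_component(fit, j))
    expect_lt(max(abs(comp - d_dense)), 1e-8)
  }
})

test_that("constraint residual vanishes where the determinant matches the target", {
  dom <- grid_domain(c(6, 6, 6))
  zf <- zero_field(dom)
  f1 <- scalar_image(dom, array(1, dom$shape))
  res <- constraint_residual(zf, f1)
  con <- constrained_voxel_set(dom)
  expect_equal(res$values[con], rep(0, sum(con)))
  expect_true(all(is.na(res$values[!con])))

  fld <- smooth_test_field(c(6, 6, 6), seed = 8)
  fdet <- jacobian_determinant(forward_jacobian(fld))
  expect_lt(max(abs(constraint_residual(fld, fdet)$values[con])), 1e-14)

  # loop oracle on a random target
  set.seed(9)
  f <- scalar_image(dom, array(runif(216, 0.5, 1.5), dom$shape))
  res2 <- constraint_residual(fld, f)$values
  or <- oracle_det_image(fld) - f$values
  expect_lt(max(abs(res2[con] - or[con])), 1e-12)
})

test_that("augmented objective reduces to the quadratic at mu = lambda = 0", {
  dom <- grid_domain(c(5, 5, 5))
  fld <- smooth_test_field(c(5, 5, 5), seed = 10)
  fid <- sample_fidelity(fld, 0.3, 0.05, seed = 11)
  f <- scalar_image(dom, array(1, dom$shape))
  ev <- augmented_objective_gradient(fld, fid, alpha = 0.5, f,
                                     lambda = 0, mu = 0)
  # direct evaluation of the regularized least-squares objective
  A <- assemble_laplacian(dom)
  val <- 0
  for (j in 1:3) {
    comp <- as.numeric(ventjac:::field_component(fld, j))
    val <- val + sum((comp[fid$linear] - fid$values[, j])^2) +
      0.5 * sum(as.numeric(A %*% comp)^2)
  }
  expect_equal(ev$value, val, tolerance = 1e-12)

  # at a constraint-satisfying point with lambda = 0, constraint terms are 0
  zf <- zero_field(dom)
  ev0 <- augmented_objective_gradient(zf, fid, 0.5, f, lambda = 0, mu = 7)
  evq <- augmented_objective_gradient(zf, fid, 0.5, f, lambda = 0, mu = 0)
  expect_equal(ev0$value, evq$value, tolerance = 1e-12)
})

test_that("analytic gradient of the augmented Lagrangian matches central differences", {
  dom <- grid_domain(c(4, 4, 4))
  fld <- smooth_test_field(c(4, 4, 4), seed = 12)
  fid <- sample_fidelity(fld, 0.4, 0.05, seed = 13)
  set.seed(14)
  f <- scalar_image(dom, array(runif(64, 0.7, 1.3), dom$shape))
  ncon <- sum(constrained_voxel_set(dom))
  lam <- runif(ncon, -1, 1)
  ev <- augmented_objective_gradient(fld, fid, 0.8, f, lambda = lam, mu = 5)
  g_an <- c(ev$gradient[[1]], ev$gradient[[2]], ev$gradient[[3]])

  x0 <- c(fld$d1, fld$d2, fld$d3)
  as_field <- function(x) displacement_field(
    dom, array(x[1:64], dom$shape), array(x[65:128], dom$shape),
    array(x[129:192], dom$shape))
  eps <- 1e-6
  idx <- sample(192, 15)
  for (k in idx) {
    xp <- x0; xp[k] <- xp[k] + eps
    xm <- x0; xm[k] <- xm[k] - eps
    g_num <- (augmented_objective_gradient(as_field(xp), fid, 0.8, f, lam,
                                           5)$value -
              augmented_objective_gradient(as_field(xm), fid, 0.8, f, lam,
                                           5)$value) / (2 * eps)
    expect_lt(abs(g_num - g_an[k]) / max(1, abs(g_an[k])), 1e-6)
  }
})

test_that("a feasible minimizer is returned unchanged: zero data, unit target", {
  dom <- grid_domain(c(5, 5, 5))
  zf <- zero_field(dom)
  fid <- sample_fidelity(zf, 0.3, 0, seed = 15)
  f1 <- scalar_image(dom, array(1, dom$shape))
  sol <- solve_constrained(fid, f1, solver_options(alpha = 0.5))
  expect_true(sol$state$converged)
  expect_lt(max(abs(sol$field$d1)), 1e-6)
  expect_lt(sol$state$max_violation, 1e-6)
})

test_that("constrained solve recovers a ground-truth Jacobian image from noisy fidelity", {
  case <- make_contraction_case(shape = c(10, 10, 10), seed = 21)
  opts <- solver_options(alpha = 0.03)
  sol <- solve_constrained(case$fidelity, case$jac, opts)
  expect_true(sol$state$converged)
  expect_lte(sol$state$max_violation, opts$constraint_tol)
  expect_gt(sol$state$min_det, 0)      # diffeomorphic at convergence
  # feasibility: det matches the target everywhere on the constrained set
  res <- constraint_residual(sol$field, case$jac)
  expect_lte(max(abs(res$values[case$constrained])), opts$constraint_tol)
})

test_that("solver is deterministic and records its convergence trajectory", {
  case <- make_contraction_case(shape = c(8, 8, 8), seed = 22)
  opts <- solver_options(alpha = 0.03)
  s1 <- solve_constrained(case$fidelity, case$jac, opts)
  s2 <- solve_constrained(case$fidelity, case$jac, opts)
  expect_identical(s1$field, s2$field)
  expect_identical(s1$state$history, s2$state$history)
  expect_true(all(diff(s1$state$history$mu) >= 0))  # penalty non-decreasing
  expect_gte(nrow(s1$state$history), 1)
})

test_that("infeasible or invalid targets are rejected, non-convergence is flagged", {
  dom <- grid_domain(c(5, 5, 5))
  zf <- zero_field(dom)
  fid <- sample_fidelity(zf, 0.3, 0, seed = 16)
  bad <- scalar_image(dom, array(-1, dom$shape))
  expect_error(solve_constrained(fid, bad, solver_options()), "invalid")

  # starved iteration budget: returns best iterate with an explicit warning
  f <- scalar_image(dom, array(0.6, dom$shape))
  opts <- solver_options(alpha = 0.03, max_outer = 1L, inner_maxit = 2L)
  expect_warning(sol <- solve_constrained(fid, f, opts), "best iterate")
  expect_false(sol$state$converged)
})
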