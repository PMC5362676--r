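make_positive_image <- function(shape = c(8, 8, 8), seed = 1, lo = 0.4,
                                hi = 1.4) {
  set.seed(seed)
  scalar_image(grid_domain(shape), array(runif(prod(shape), lo, hi), shape))
}

test_that("smoothed constraint preserves constants and rejects nonpositive input", {
  dom <- grid_domain(c(6, 6, 6))
  const <- scalar_image(dom, array(0.8, dom$shape))
  expect_equal(smoothed_constraint(const, 2)$values, const$values)
  expect_equal(smoothed_constraint(const, 0)$values, const$values)

  bad <- const; bad$values[3, 3, 3] <- 0
  expect_error(smoothed_constraint(bad, 1), "strictly positive")

  img <- make_positive_image(seed = 2)
  expect_lt(max(abs(smoothed_constraint(img, 1)$values -
                      oracle_gaussian_smooth(img$values, 1))), 1e-10)
})

test_that("clip_to_bounds implements the three-case clip", {
  dom <- grid_domain(c(3, 2, 2))
  img <- scalar_image(dom, array(c(0.4, 0.8, 1.2), dom$shape))
  spec <- bound_spec(0.5, 1.0, sigma = 0)
  expect_equal(clip_to_bounds(img, spec)$values[, 1, 1], c(0.5, 0.8, 1.0))

  # the reference mean unconstrained value under the tighter contraction
  img79 <- scalar_image(dom, array(0.79, dom$shape))
  expect_equal(clip_to_bounds(img79, bound_spec(0.5, 0.75))$values[1, 1, 1],
               0.75)

  inside <- scalar_image(dom, array(0.7, dom$shape))
  expect_equal(clip_to_bounds(inside, spec)$values, inside$values)
})

test_that("bound constraint output always lies in [LB, UB]", {
  spec <- bound_spec(0.5, 1.0, sigma = 1.5)
  img3 <- make_positive_image(seed = 3)
  ref <- gaussian_smooth(clip_to_bounds(img3, spec), 1.5)$values
  expect_equal(bound_constraint(img3, spec)$values, ref)
  for (s in 1:20) {
    img <- make_positive_image(c(6, 6, 6), seed = 100 + s, lo = 0.1, hi = 2)
    out <- bound_constraint(img, spec)$values
    expect_gte(min(out), spec$LB)
    expect_lte(max(out), spec$UB)
  }
  # sigma = 0 reduces to the clip
  img <- make_positive_image(seed = 4)
  expect_equal(bound_constraint(img, bound_spec(0.5, 1, 0))$values,
               clip_to_bounds(img, bound_spec(0.5, 1, 0))$values)
})

test_that("linear map fit matches exact affine relations and the normal equations", {
  img <- make_positive_image(seed = 5)
  fit_id <- fit_linear_map(img, img)
  expect_equal(fit_id$a, 1, tolerance = 1e-10)
  expect_equal(fit_id$b, 0, tolerance = 1e-10)

  neg <- scalar_image(img$domain, -img$values + 3)
  fit_neg <- fit_linear_map(neg, img)
  expect_equal(fit_neg$a, -1, tolerance = 1e-10)
  expect_equal(fit_neg$b, 3, tolerance = 1e-10)

  set.seed(6)
  dom <- grid_domain(c(50, 2, 2))
  g <- scalar_image(dom, array(rnorm(200), dom$shape))
  j <- scalar_image(dom, array(rnorm(200, 1), dom$shape))
  fit <- fit_linear_map(g, j)
  X <- cbind(1, g$values[TRUE])
  beta <- solve(t(X) %*% X, t(X) %*% j$values[TRUE])  # normal equations
  expect_equal(c(fit$b, fit$a), c(beta), tolerance = 1e-10)

  const <- scalar_image(dom, array(1, dom$shape))
  expect_error(fit_linear_map(const, j), "constant")
})

test_that("fit_linear_map minimizes the least-squares objective locally", {
  set.seed(7)
  dom <- grid_domain(c(40, 2, 2))
  g <- scalar_image(dom, array(rnorm(160), dom$shape))
  j <- scalar_image(dom, array(0.8 - 0.3 * g$values + rnorm(160, sd = 0.2),
                               dom$shape))
  fit <- fit_linear_map(g, j)
  rss <- function(a, b) sum((a * g$values + b - j$values)^2)
  r0 <- rss(fit$a, fit$b)
  for (da in c(-1e-3, 0, 1e-3)) for (db in c(-1e-3, 0, 1e-3))
    expect_gte(rss(fit$a + da, fit$b + db), r0 - 1e-12)
})

test_that("correlation constraint is an affine image of g, perfectly correlated", {
  img <- make_positive_image(seed = 8)
  g <- scalar_image(img$domain, array(rnorm(512, 2), img$domain$shape))
  map <- fit_linear_map(g, img)
  f <- correlation_constraint(g, map)
  expect_equal(f$values, map$a * g$values + map$b, tolerance = 1e-14)
  expect_equal(abs(image_correlation(f, g)), 1, tolerance = 1e-12)

  gc_const <- scalar_image(img$domain, array(2, img$domain$shape))
  fc <- correlation_constraint(gc_const, map)
  expect_true(all(fc$values == map$a * 2 + map$b))
})

test_that("non-positive correlation targets fail loudly unless floored", {
  dom <- grid_domain(c(4, 4, 4))
  g <- scalar_image(dom, array(seq(-2, 2, length.out = 64), dom$shape))
  map <- structure(list(a = 1, b = 0), class = "linear_map")
  expect_error(correlation_constraint(g, map), "non-positive at")
  f <- correlation_constraint(g, map, eps_floor = 1e-3)
  expect_gte(min(f$values), 1e-3)
  expect_gt(attr(f, "floored_voxels"), 0)
})

test_that("validate_constraint reports positivity violations with counts", {
  img <- make_positive_image(seed = 9)
  rep_ok <- validate_constraint(img)
  expect_true(rep_ok$ok)
  expect_equal(rep_ok$min, min(img$values))
  expect_equal(rep_ok$max, max(img$values))

  img$values[2, 3, 4] <- 0
  rep_bad <- validate_constraint(img)
  expect_false(rep_bad$ok)
  expect_equal(rep_bad$n_nonpositive, 1)
  expect_equal(unname(rep_bad$violations[1, ]), c(2, 3, 4))
})
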