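test_that("domain and field constructors validate their invariants", {
  expect_error(grid_domain(c(1, 4, 4)), "shape")
  expect_error(grid_domain(c(4, 4, 4), spacing = c(1, -1, 1)), "spacing")
  expect_error(grid_domain(c(4, 4, 4), mask = array(FALSE, c(4, 4, 4))),
               "TRUE voxel")
  dom <- grid_domain(c(4, 4, 4))
  bad <- array(0, c(4, 4, 4)); bad[1] <- Inf
  expect_error(displacement_field(dom, bad, bad * 0, bad * 0), "non-finite")
  expect_error(scalar_image(dom, array(Inf, c(4, 4, 4))), "infinite")
})

test_that("zero displacement gives identity Jacobian and zero ventilation", {
  dom <- grid_domain(c(5, 4, 6))
  jac <- forward_jacobian(zero_field(dom))
  for (i in 1:3) for (j in 1:3)
    expect_equal(jac[[paste0("J", i, j)]],
                 array(as.numeric(i == j), dim = dom$shape))
  expect_equal(jacobian_determinant(jac)$values, array(1, dom$shape))
  expect_equal(ventilation_image(zero_field(dom))$values, array(0, dom$shape))
})

test_that("axis-doubling affine field has determinant 2 with in-grid forward neighbors", {
  dom <- grid_domain(c(8, 8, 8))
  fld <- make_affine_field(diag(c(2, 1, 1)), c(0, 0, 0), dom)$field
  dv <- jacobian_determinant(forward_jacobian(fld))$values
  expect_equal(dv[1:7, , ], array(2, c(7, 8, 8)))
  # replicated boundary along axis 1: forward difference 0, diagonal 1
  expect_equal(dv[8, , ], matrix(1, 8, 8))
  expect_equal(ventilation_image(fld)$values[3, 3, 3], 1)  # 100% increase
})

test_that("affine exactness: determinant equals det(M) for random positive-determinant affines", {
  dom <- grid_domain(c(6, 6, 6))
  set.seed(42)
  for (rep in 1:10) {
    M <- diag(3) + matrix(rnorm(9, sd = 0.15), 3, 3)
    if (det(M) <= 0) next
    fld <- make_affine_field(M, rnorm(3), dom)$field
    dv <- jacobian_determinant(forward_jacobian(fld))$values[1:5, 1:5, 1:5]
    expect_lt(max(abs(dv - det(M))) / abs(det(M)), 1e-12)
  }
  # rigid shift: determinant 1, ventilation 0 everywhere (boundary included)
  shift <- make_affine_field(diag(3), c(3, -1, 2), dom)$field
  expect_equal(ventilation_image(shift)$values, array(0, dom$shape))
})

test_that("forward Jacobian and determinant match the per-voxel loop oracle", {
  fld <- smooth_test_field(c(8, 8, 8), seed = 3)
  jac <- forward_jacobian(fld)
  dv <- jacobian_determinant(jac)$values
  ov <- oracle_det_image(fld)
  expect_lt(max(abs(dv - ov)), 1e-12)
  n <- fld$domain$shape
  set.seed(5)
  for (rep in 1:20) {
    v <- c(sample(n[1], 1), sample(n[2], 1), sample(n[3], 1))
    J_or <- oracle_jacobian_at(fld, v[1], v[2], v[3])
    for (i in 1:3) for (j in 1:3)
      expect_equal(jac[[paste0("J", i, j)]][v[1], v[2], v[3]], J_or[i, j],
                   tolerance = 1e-14)
  }
})

test_that("determinant of arbitrary 3x3 entries matches cofactor expansion", {
  set.seed(9)
  for (rep in 1:50) {
    a <- rnorm(9)
    d_pkg <- ventjac:::det3(a[1], a[2], a[3], a[4], a[5], a[6],
                            a[7], a[8], a[9])
    d_ref <- det(matrix(a, 3, 3, byrow = TRUE))
    expect_lt(abs(d_pkg - d_ref) / max(1, abs(d_ref)), 1e-12)
  }
})

test_that("displacement_gradient matches linear fields and Jacobian rows", {
  dom <- grid_domain(c(6, 6, 6))
  co <- ventjac:::coordinate_arrays(dom)
  z <- array(0, dom$shape)
  fld <- displacement_field(dom, co$x2, z, z)   # d1(x) = x2
  expect_equal(displacement_gradient(fld, 1, c(3, 3, 3)), c(0, 1, 0))
  expect_equal(displacement_gradient(fld, 2, c(3, 3, 3)), c(0, 0, 0))
  expect_error(displacement_gradient(fld, 1, c(7, 1, 1)), "outside")

  rnd <- smooth_test_field(c(6, 6, 6), seed = 8)
  jac <- forward_jacobian(rnd)
  for (v in list(c(2, 3, 4), c(6, 6, 6), c(1, 1, 1))) {
    for (i in 1:3) {
      g <- displacement_gradient(rnd, i, v)
      row <- vapply(1:3, function(j)
        jac[[paste0("J", i, j)]][v[1], v[2], v[3]], numeric(1)) -
        (1:3 == i)
      expect_equal(g, row, tolerance = 1e-14)
    }
  }
})

test_that("gaussian smoothing preserves constants, identity at sigma 0, matches brute force", {
  dom <- grid_domain(c(8, 8, 8))
  const <- scalar_image(dom, array(0.8, dom$shape))
  expect_equal(gaussian_smooth(const, 2.5)$values, const$values)

  set.seed(11)
  img <- scalar_image(dom, array(runif(512), dom$shape))
  expect_equal(gaussian_smooth(img, 0)$values, img$values)
  expect_error(gaussian_smooth(img, -1), "sigma")

  sm <- gaussian_smooth(img, 1)$values
  or <- oracle_gaussian_smooth(img$values, 1)
  expect_lt(max(abs(sm - or)), 1e-10)

  # bound preservation: output stays inside the input range
  expect_gte(min(sm), min(img$values))
  expect_lte(max(sm), max(img$values))
})

test_that("mask-renormalized smoothing ignores voxels outside the mask", {
  set.seed(13)
  mask <- array(runif(6^3) > 0.3, c(6, 6, 6))
  mask[2, 2, 2] <- TRUE
  dom <- grid_domain(c(6, 6, 6), mask = mask)
  vals <- array(runif(6^3), c(6, 6, 6))
  vals[!mask] <- 1e6  # poison outside-mask voxels; they must not leak in
  img <- scalar_image(dom, vals)
  sm <- gaussian_smooth(img, 1)
  or <- oracle_gaussian_smooth(vals, 1, mask)
  expect_lt(max(abs(sm$values[mask] - or[mask])), 1e-10)
  expect_true(all(is.na(sm$values[!mask])))
  expect_lte(max(sm$values[mask]), 1)
})
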