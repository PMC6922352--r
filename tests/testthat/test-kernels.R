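test_that("gaussian kernels normalize to unit sum and respect anisotropy", {
  k <- build_gaussian_kernel(c(1, 1, 1), c(0.7, 0.3), support = 9)
  expect_equal(sum(k$weights), 1, tolerance = 1e-6)
  # isotropic: maximum at the centre voxel
  expect_equal(which.max(k$weights), (prod(dim(k$weights)) + 1) %/% 2)
  # anisotropic sigma (1,1,4) along z: discrete second moments ~ 16x
  ka <- build_gaussian_kernel(c(1, 1, 4), c(0, pi / 2), support = 21)
  gr <- expand.grid(x = -10:10, y = -10:10, z = -10:10)
  w <- as.vector(ka$weights)
  vz <- sum(w * gr$z^2); vx <- sum(w * gr$x^2)
  expect_gt(vz / vx, 12)
  expect_lt(vz / vx, 20)
  expect_error(build_gaussian_kernel(c(1, 1, 1), c(0, 0), support = 8),
               "odd")
})

test_that("tubular kernels are cropped, zero-sum and unit-norm", {
  k <- build_tubular_kernel(c(1, 1, 4), c(0, pi / 2), support = 33)
  expect_equal(sum(k$weights), 0, tolerance = 1e-6)
  expect_equal(sqrt(sum(k$weights^2)), 1, tolerance = 1e-6)
  # crop plane: 0.01 tail of the 1D profile, floor(qnorm(.99) * 4) = 9
  expect_equal(k$crop_extent, 9)
  # phi = pi/2 orients the tube along z: planes |z| > 9 are all zero
  a <- k$weights
  expect_true(all(a[, , c(1:7, 27:33)] == 0))
  expect_true(any(a[, , 8] != 0))
  expect_error(build_tubular_kernel(c(4, 4, 1), c(0, 0)), "sigma_z")
  expect_error(build_tubular_kernel(c(1, 1, 4), c(0, 0), support = 15),
               "too small")
})

test_that("rotating a tubular kernel by pi about the axis changes nothing", {
  k1 <- build_tubular_kernel(c(1, 1, 2), c(0.4, 0.2), support = 13)
  k2 <- build_tubular_kernel(c(1, 1, 2), c(0.4 + pi, -0.2), support = 13)
  expect_equal(k1$weights, k2$weights, tolerance = 1e-6)
})

test_that("orientation bank enumerates the hemisphere grid", {
  b6 <- orientation_bank(pi / 6)
  expect_length(b6, 32)   # 6 azimuths x 5 elevations + 2 poles
  b2 <- orientation_bank(pi / 2)
  expect_length(b2, 4)
  for (tp in b6) expect_equal(sqrt(sum(orientation_eta(tp)^2)), 1,
                              tolerance = 1e-12)
  # no duplicated directions
  etas <- sapply(b6, function(tp) paste(round(orientation_eta(tp), 8),
                                        collapse = "|"))
  expect_equal(anyDuplicated(etas), 0L)
  expect_error(orientation_bank(1), "divide")
})

test_that("every bank kernel satisfies the normalization contracts", {
  bank <- tubular_bank(c(1, 1, 2), orientation_bank(pi / 3), support = 13)
  for (k in bank) {
    expect_lt(abs(sum(k$weights)), 1e-6)
    expect_lt(abs(sqrt(sum(k$weights^2)) - 1), 1e-6)
  }
})

test_that("aligned tubes outscore orthogonal tubes by more than 2x", {
  d <- c(24L, 24L, 24L)
  dark_cyl <- function(axis) {
    a <- array(0, d)
    for (u in 1:24) for (v in 1:24) {
      if ((u - 12)^2 + (v - 12)^2 <= 4) {
        if (axis == "z") a[u, v, ] <- -1000 else a[, u, v] <- -1000
      }
    }
    a
  }
  kz <- build_tubular_kernel(c(1, 1, 4), c(0, pi / 2), support = 21)
  rz <- appearance_map(scalar_volume(dark_cyl("z")), list(kz))
  rx <- appearance_map(scalar_volume(dark_cyl("x")), list(kz))
  expect_gt(rz$data[12, 12, 12] / rx$data[12, 12, 12], 2)
})
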