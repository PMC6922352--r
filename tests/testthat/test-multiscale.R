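test_that("max pooling agrees with brute-force block maxima", {
  set.seed(21)
  v <- scalar_volume(array(rnorm(216), c(6, 6, 6)), spacing = c(1, 1, 1))
  mp <- max_pool(v)
  expect_equal(dim(mp$data), c(3L, 3L, 3L))
  expect_equal(mp$spacing, c(2, 2, 2))
  for (i in 1:3) for (j in 1:3) for (k in 1:3)
    expect_equal(mp$data[i, j, k],
                 max(v$data[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j),
                            (2 * k - 1):(2 * k)]))
})

test_that("odd extents are padded so padding never wins", {
  v <- scalar_volume(array(seq_len(5 * 5 * 5), c(5, 5, 5)))
  mp <- max_pool(v)
  expect_equal(dim(mp$data), c(3L, 3L, 3L))
  expect_equal(mp$data[3, 3, 3], 125)  # corner block holds only voxel 125
  # constant volumes stay constant
  cv <- max_pool(scalar_volume(array(7, c(4, 4, 4))))
  expect_true(all(cv$data == 7))
})

test_that("un-pooling broadcasts blocks and inverts pooling as a superset", {
  m <- binary_mask(array(FALSE, c(2, 2, 2)))
  m$data[2, 1, 1] <- TRUE
  up <- un_pool(m, c(4L, 4L, 4L))
  expect_equal(sum(up$data), 8)
  expect_true(all(up$data[3:4, 1:2, 1:2]))
  set.seed(22)
  for (rep in 1:25) {
    r <- binary_mask(array(runif(8^3) < 0.3, c(8, 8, 8)))
    up2 <- un_pool(max_pool(r), c(8L, 8L, 8L))
    expect_true(all(up2$data[r$data]))
  }
  expect_error(un_pool(m, c(5L, 4L, 4L)), "incompatible")
  z <- binary_mask(array(FALSE, c(3, 3, 3)))
  expect_equal(sum(un_pool(z, c(6L, 6L, 6L))$data), 0)
})

test_that("multiscale appearance takes the best level per voxel", {
  set.seed(23)
  E0 <- scalar_volume(array(runif(6^3), c(6, 6, 6)))
  class(E0) <- c("appearance_map", class(E0))
  E1 <- scalar_volume(array(runif(27), c(3, 3, 3)), spacing = c(2, 2, 2))
  class(E1) <- c("appearance_map", class(E1))
  ms <- multiscale_appearance(list(list(E = E0), list(E = E1)))
  expect_true(all(ms$data >= E0$data))
  expect_equal(ms$data[1, 1, 1], max(E0$data[1, 1, 1], E1$data[1, 1, 1]))
})

test_that("initial segmentation combines levels with OR semantics", {
  # thick dark tube: weak for the sigma_z=2 kernel at level 0, strong at
  # level 1 after pooling halves its radius
  d <- c(32L, 32L, 48L)
  a <- array(ifelse(cylinder_mask(d, 6), -1000, 0), d)
  set.seed(24)
  a <- a + rnorm(length(a), 0, 5)
  ct <- scalar_volume(array(a, d))
  bank <- tubular_bank(c(1, 1, 2), orientation_bank(pi / 2), support = 13)
  search <- threshold_search(300, 6000, 50, 0)
  init <- suppressWarnings(
    initial_segmentation(ct, levels = 1, search = search, bank = bank,
                         root_hint = c(16, 16, 47)))
  # SegI contains the level-0 binarization at its own threshold
  lvl0 <- threshold_segment(init$levels[[1]]$E, init$levels[[1]]$thopt)
  expect_true(all(init$segI$data[lvl0$data]))
  # and the un-pooled coarse level
  expect_true(all(init$segI$data[init$segUp1$data]))
  # the thick tube is recovered through the coarse level
  core <- cylinder_mask(d, 2)
  expect_gt(mean(init$segI$data[core]), 0.8)
  # deterministic: same inputs, same output
  init2 <- suppressWarnings(
    initial_segmentation(ct, levels = 1, search = search, bank = bank,
                         root_hint = c(16, 16, 47)))
  expect_identical(init$segI$data, init2$segI$data)
})
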