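test_that("tree generation follows the binary-branching recursion", {
  g1 <- generate_tree(phantom_spec(generations = 1, seed = 3))
  expect_equal(g1$branch_count, 1)
  g3 <- generate_tree(phantom_spec(seed = 3))
  expect_equal(g3$branch_count, 7)           # 2^3 - 1 segments
  expect_equal(sum(g3$segments$generation == 3), 4)
  # deterministic under a fixed seed
  again <- generate_tree(phantom_spec(seed = 3))
  expect_identical(g3$segments, again$segments)
  other <- generate_tree(phantom_spec(seed = 4))
  expect_false(identical(g3$segments, other$segments))
  # a tree that cannot fit errors with the offending generation
  expect_error(generate_tree(phantom_spec(generations = 6,
                                          extents = c(40L, 40L, 48L))),
               "generation")
})

test_that("rasterization realizes the three-compartment intensity model", {
  spec <- phantom_spec(noise_sd = 0, seed = 5)
  truth <- generate_tree(spec)
  ras <- rasterize_phantom(truth, spec)
  vals <- sort(unique(as.vector(ras$ct$data)))
  expect_identical(vals, c(-1000, -850, 0))
  # lumen mask marks exactly the lumen-intensity voxels
  expect_identical(ras$truth$lumen_mask$data, ras$ct$data == -1000)
  # noise leaves the lumen mask itself untouched
  spec2 <- phantom_spec(noise_sd = 15, seed = 5)
  ras2 <- rasterize_phantom(generate_tree(spec2), spec2)
  expect_identical(ras2$truth$lumen_mask$data, ras$truth$lumen_mask$data)
})

test_that("leakage injection is deterministic and bookkeeps its volume", {
  spec <- phantom_spec(seed = 6)
  ras <- rasterize_phantom(generate_tree(spec), spec)
  inj0 <- inject_leakage(ras$ct, ras$truth, n_blobs = 0)
  expect_identical(inj0$ct$data, ras$ct$data)
  inj1 <- inject_leakage(ras$ct, ras$truth, n_blobs = 1)
  leak <- inj1$truth$leakage_mask$data
  expect_gt(sum(leak), 0)
  expect_false(any(leak & ras$truth$lumen_mask$data)) # disjoint from lumen
  expect_true(all(inj1$ct$data[leak] == spec$lumen_hu))
  inj1b <- inject_leakage(ras$ct, ras$truth, n_blobs = 1)
  expect_identical(inj1$ct$data, inj1b$ct$data)
})

test_that("a bridging blob creates a cycle in the reference segmentation", {
  spec <- phantom_spec(generations = 2, extents = c(72L, 72L, 96L),
                       root_radius = 3, radius_decay = 0.67,
                       root_length = 24, length_decay = 1,
                       angle_range = c(pi / 6, pi / 4), seed = 2)
  ras <- rasterize_phantom(generate_tree(spec), spec)
  inj <- inject_leakage(ras$ct, ras$truth, n_blobs = 1, bridge = TRUE)
  segL <- binary_mask(inj$truth$lumen_mask$data | inj$truth$leakage_mask$data,
                      inj$ct$spacing)
  sg <- skeletonize(segL, split_chains = TRUE, close_gaps = TRUE)
  ag <- direct_graph(sg, find_root(segL, sg, hint = inj$truth$root_voxel))
  expect_gt(complexity(ag), 0)
  # without the blob the reference segmentation is a tree
  seg0 <- ras$truth
  ras0 <- rasterize_phantom(generate_tree(spec), spec)
  sgc <- skeletonize(ras0$truth$lumen_mask, close_gaps = TRUE)
  agc <- direct_graph(sgc, find_root(ras0$truth$lumen_mask, sgc,
                                     hint = ras0$truth$root_voxel))
  expect_equal(complexity(agc), 0)
})

test_that("metrics score a perfect segmentation perfectly", {
  spec <- phantom_spec(seed = 7)
  ras <- rasterize_phantom(generate_tree(spec), spec)
  m <- exact_metrics(ras$truth$lumen_mask, ras$truth)
  expect_equal(m$branch_count, 7)
  expect_equal(m$branch_pct, 100)
  expect_equal(m$tree_length_pct, 100)
  expect_equal(m$leak_count, 0)
  expect_equal(m$fpr_pct, 0)
  # empty segmentation scores zero everywhere
  empty <- binary_mask(array(FALSE, dim(ras$ct$data)), ras$ct$spacing)
  m0 <- exact_metrics(empty, ras$truth)
  expect_equal(m0$branch_count, 0)
  expect_equal(m0$tree_length_pct, 0)
  expect_equal(m0$leak_count, 0)
})

test_that("an external blob is counted as one leak with its physical volume", {
  spec <- phantom_spec(seed = 8)
  ras <- rasterize_phantom(generate_tree(spec), spec)
  seg <- ras$truth$lumen_mask
  # 100 voxels far from the airway: 100 * 0.5^3 mm^3
  blob <- seg$data
  blob[2:6, 2:6, 2:5] <- TRUE  # 5*5*4 = 100 voxels
  m <- exact_metrics(binary_mask(blob, seg$spacing), ras$truth)
  expect_equal(m$leak_count, 1)
  expect_equal(m$leak_volume_mm3, 12.5)
  expect_gt(m$fpr_pct, 0)
  expect_error(exact_metrics(binary_mask(blob, c(1, 1, 1)), ras$truth),
               "spacing")
})
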