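two_tip_masks <- function() {
  d <- c(20L, 20L, 20L)
  segUp1 <- array(FALSE, d); segUp1[8:13, 8:13, 8:20] <- TRUE
  segI <- segUp1
  segI[10:11, 10:11, 4:7] <- TRUE            # distal tip below the core
  segI[3:5, 10:11, 10:12] <- TRUE            # second, disjoint tip
  list(segI = binary_mask(segI), segUp1 = binary_mask(segUp1), dim = d)
}

test_that("distal components are the connected parts beyond the coarse core", {
  m <- two_tip_masks()
  comps <- distal_components(m$segI, m$segUp1)
  expect_length(comps, 2)
  expect_setequal(vapply(comps, function(cc) cc$n_voxels, numeric(1)),
                  c(16, 18))
  # identical masks leave nothing distal
  expect_length(distal_components(m$segUp1, m$segUp1), 0)
  # single-voxel speckle is dropped by the size floor
  spk <- m$segUp1
  spk$data[1, 1, 1] <- TRUE
  expect_length(distal_components(spk, m$segUp1, min_voxels = 2), 0)
})

test_that("the ROI is the Voronoi cell of the component", {
  d <- c(11L, 5L, 5L)
  a <- array(FALSE, d); a[1, 1, 1] <- TRUE
  b <- array(FALSE, d); b[11, 1, 1] <- TRUE
  segI <- binary_mask(a | b)
  comp <- structure(list(mask = binary_mask(a), n_voxels = 1, id = 1),
                    class = "distal_component")
  roi <- roi_mask(comp, segI)
  # halfspace i <= 6 including the tie plane
  expect_true(all(roi$data[1:6, , ]))
  expect_false(any(roi$data[7:11, , ]))
  # the component is always inside its own ROI
  expect_true(all(roi$data[comp$mask$data]))
})

test_that("ROI equals the two-distance-transform comparison on random masks", {
  set.seed(41)
  d <- c(12L, 12L, 12L)
  for (rep in 1:10) {
    segI <- array(runif(prod(d)) < 0.08, d)
    if (sum(segI) < 4) next
    lab <- array(picasso:::cpp_label_components(as.vector(segI), d, 26L), d)
    cc1 <- lab == 1
    if (!any(segI & !cc1)) next
    comp <- structure(list(mask = binary_mask(cc1), n_voxels = sum(cc1),
                           id = 1), class = "distal_component")
    roi <- roi_mask(comp, binary_mask(segI))
    cvox <- which(cc1, arr.ind = TRUE)
    rvox <- which(segI & !cc1, arr.ind = TRUE)
    allv <- as.matrix(expand.grid(i = 1:12, j = 1:12, k = 1:12))
    dc <- apply(allv, 1, function(p) min(colSums((t(cvox) - p)^2)))
    dr <- apply(allv, 1, function(p) min(colSums((t(rvox) - p)^2)))
    expect_identical(as.vector(roi$data), dc <= dr)
  }
})

test_that("ROIs of all components cover the whole volume", {
  m <- two_tip_masks()
  comps <- distal_components(m$segI, m$segUp1)
  covered <- array(FALSE, m$dim)
  for (cc in comps) covered <- covered | roi_mask(cc, m$segI)$data
  # plus the proximal remainder's own Voronoi cell
  prox <- structure(list(mask = m$segUp1, n_voxels = sum(m$segUp1$data),
                         id = 0), class = "distal_component")
  covered <- covered | roi_mask(prox, m$segI)$data
  expect_true(all(covered))
})

test_that("branch refinement extends a locally faint distal tube", {
  # tube whose distal half has weaker wall contrast: the global threshold
  # truncates it, the local one recovers it
  d <- c(24L, 24L, 48L)
  a <- array(0, d)
  cyl <- cylinder_mask(d, 2)
  a[cyl] <- -1000
  a[cyl & rep(rep(seq_len(d[3]) <= 20, each = d[1] * d[2]), 1)] <- -450
  ct <- scalar_volume(array(a, d))
  bank <- tubular_bank(c(1, 1, 2), orientation_bank(pi / 2), support = 13)
  E0 <- appearance_map(ct, bank)
  th_global <- 2500 # segments only the strong proximal part
  segI <- threshold_segment(E0, th_global)
  # coarse core: the proximal half
  segUp1 <- binary_mask(segI$data &
                          rep(rep(seq_len(d[3]) > 30, each = d[1] * d[2]), 1))
  search <- threshold_search(800, 6000, 50, 0)
  ref <- suppressWarnings(refine_all(segI, segUp1, E0, search = search))
  expect_true(all(ref$mask$data[segI$data]))       # never shrinks
  # the refined mask reaches farther down the faint half than SegI
  reach <- function(m) min(which(apply(m$data, 3, any)))
  expect_lt(reach(ref$mask), reach(segI))
  # local thresholds sit below the global truncation threshold
  ths <- na.omit(vapply(ref$branches, function(b) b$threshold, numeric(1)))
  expect_true(length(ths) >= 1 && all(ths < th_global))
})

test_that("refinement is order-independent and idempotent in shape", {
  m <- two_tip_masks()
  set.seed(42)
  E0 <- scalar_volume(array(runif(prod(m$dim), 0, 100), m$dim))
  class(E0) <- c("appearance_map", class(E0))
  search <- threshold_search(900, 2000, 50, 0) # nothing above th_min: fallbacks
  ref <- suppressWarnings(refine_all(m$segI, m$segUp1, E0, search = search))
  # all-fallback refinement reproduces SegI exactly
  expect_identical(ref$mask$data, m$segI$data)
  expect_true(all(vapply(ref$branches, function(b) b$fallback, logical(1))))
})
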