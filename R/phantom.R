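# Synthetic bronchial-tree phantoms. A recursive binary tree of straight
# segments is rasterized into a CT-like volume: dark lumen, a thin bright
# wall shell, parenchyma background and additive Gaussian noise. Ground
# truth (centerline tree, radii, lumen mask, injected leakage) is kept
# alongside so segmentations can be scored with EXACT09-style metrics
# without any clinical data.

#' Phantom specification
#'
#' Defaults give a G = 3 tree in a 64 x 64 x 96 grid at 0.5 mm isotropic
#' spacing: root radius 4 voxels decaying by 0.75 per generation, lumen
#' -1000 HU inside a 1-voxel 0 HU wall, parenchyma -850 HU, noise sd 15 HU.
#'
#' @param generations Number of branching generations `G >= 1`.
#' @param extents Volume extents in voxels.
#' @param spacing Voxel spacing in mm.
#' @param root_radius Trachea radius in voxels.
#' @param radius_decay Per-generation radius factor.
#' @param root_length Trachea length in voxels.
#' @param length_decay Per-generation length factor.
#' @param angle_range Branching polar angle range in radians.
#' @param lumen_hu,wall_hu,parenchyma_hu Intensity model, HU.
#' @param wall_thickness Wall shell thickness in voxels.
#' @param noise_sd Additive Gaussian noise sd, HU.
#' @param seed RNG seed; the phantom is deterministic given the seed.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(generations = 3, extents = c(64L, 64L, 96L),
                         spacing = c(0.5, 0.5, 0.5), root_radius = 4,
                         radius_decay = 0.75, root_length = 24,
                         length_decay = 0.8,
                         angle_range = c(pi / 9, pi / 4.5),
                         lumen_hu = -1000, wall_hu = 0, parenchyma_hu = -850,
                         wall_thickness = 1, noise_sd = 15, seed = 1L) {
  if (generations < 1) stop("generations must be >= 1")
  if (root_radius < 1) stop("root radius must be at least 1 voxel")
  if (!(lumen_hu < parenchyma_hu && parenchyma_hu < wall_hu))
    stop("intensity model must satisfy lumen < parenchyma < wall")
  structure(list(generations = generations, extents = as.integer(extents),
                 spacing = spacing, root_radius = root_radius,
                 radius_decay = radius_decay, root_length = root_length,
                 length_decay = length_decay, angle_range = angle_range,
                 lumen_hu = lumen_hu, wall_hu = wall_hu,
                 parenchyma_hu = parenchyma_hu,
                 wall_thickness = wall_thickness, noise_sd = noise_sd,
                 seed = as.integer(seed)), class = "phantom_spec")
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv())
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

# unit vector orthogonal pair spanning the plane normal to v
ortho_frame <- function(v) {
  v <- v / sqrt(sum(v^2))
  a <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u1 <- a - sum(a * v) * v
  u1 <- u1 / sqrt(sum(u1^2))
  u2 <- c(v[2] * u1[3] - v[3] * u1[2],
          v[3] * u1[1] - v[1] * u1[3],
          v[1] * u1[2] - v[2] * u1[1])
  list(u1 = u1, u2 = u2)
}

#' Generate a bronchial-tree centerline phantom
#'
#' Recursive binary tree of straight segments: the root starts at the top
#' centre of the volume pointing down; each segment spawns two children
#' rotated by a branching angle sampled from `angle_range` at opposite
#' azimuths, with radius and length decayed per generation. Deterministic
#' given `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return A `phantom_truth`: data frame of segments (start/end voxel
#'   coordinates, radius, generation, parent), total length, branch count
#'   and the spec.
#' @export
generate_tree <- function(spec) {
  ext <- spec$extents
  segs <- NULL
  with_seed(spec$seed, {
    start <- c(ext[1] / 2, ext[2] / 2, ext[3] - 2)
    recurse <- function(p0, dir, radius, len, gen, parent) {
      p1 <- p0 + dir * len
      margin <- radius + spec$wall_thickness + 1
      if (any(p1 < margin) || any(p1 > ext - margin + 1))
        stop("phantom tree escapes the volume at generation ", gen,
             "; enlarge extents or shorten branches")
      id <- nrow(segs %||% data.frame()) + 1L
      segs <<- rbind(segs, data.frame(
        id = id, parent = parent, generation = gen,
        x0 = p0[1], y0 = p0[2], z0 = p0[3],
        x1 = p1[1], y1 = p1[2], z1 = p1[3], radius = radius))
      if (gen < spec$generations) {
        ang <- runif(1, spec$angle_range[1], spec$angle_range[2])
        az <- runif(1, 0, 2 * pi)
        fr <- ortho_frame(dir)
        for (s in c(1, -1)) {
          lat <- cos(az) * fr$u1 + sin(az) * fr$u2
          child <- cos(ang) * dir + s * sin(ang) * lat
          child <- child / sqrt(sum(child^2))
          recurse(p1, child, radius * spec$radius_decay,
                  len * spec$length_decay, gen + 1L, id)
        }
      }
    }
    recurse(start, c(0, 0, -1), spec$root_radius, spec$root_length, 1L, 0L)
  })
  lens_mm <- sqrt(((segs$x1 - segs$x0) * spec$spacing[1])^2 +
                  ((segs$y1 - segs$y0) * spec$spacing[2])^2 +
                  ((segs$z1 - segs$z0) * spec$spacing[3])^2)
  structure(list(segments = segs, branch_count = nrow(segs),
                 total_length_mm = sum(lens_mm), lengths_mm = lens_mm,
                 root_voxel = round(c(ext[1] / 2, ext[2] / 2, ext[3] - 2)),
                 leakage_mask = NULL, lumen_mask = NULL, spec = spec),
            class = "phantom_truth")
}

# distance from every voxel to a segment, computed on a bounding box only
segment_distance_update <- function(dmin, rad, seg, ext, pad) {
  p0 <- c(seg$x0, seg$y0, seg$z0); p1 <- c(seg$x1, seg$y1, seg$z1)
  lo <- pmax(floor(pmin(p0, p1)) - pad, 1)
  hi <- pmin(ceiling(pmax(p0, p1)) + pad, ext)
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  gx <- rep(xs, times = length(ys) * length(zs))
  gy <- rep(rep(ys, each = length(xs)), times = length(zs))
  gz <- rep(zs, each = length(xs) * length(ys))
  v <- p1 - p0
  L2 <- sum(v^2)
  t <- ((gx - p0[1]) * v[1] + (gy - p0[2]) * v[2] + (gz - p0[3]) * v[3]) / L2
  t <- pmin(pmax(t, 0), 1)
  dx <- gx - (p0[1] + t * v[1])
  dy <- gy - (p0[2] + t * v[2])
  dz <- gz - (p0[3] + t * v[3])
  dist <- sqrt(dx^2 + dy^2 + dz^2)
  idx <- gx + (gy - 1) * ext[1] + (gz - 1) * ext[1] * ext[2]
  better <- dist < dmin[idx]
  dmin[idx[better]] <- dist[better]
  rad[idx[better]] <- seg$radius
  list(dmin = dmin, rad = rad)
}

#' Rasterize a phantom into a CT-like volume
#'
#' Voxels within the local branch radius of the centerline get the lumen
#' intensity, a shell of `wall_thickness` around them the wall intensity,
#' everything else parenchyma; Gaussian noise is added on top
#' (deterministic given the spec seed). Returns the volume together with
#' the truth updated with the exact lumen mask.
#'
#' @param truth A `phantom_truth` from [generate_tree()].
#' @param spec The matching [phantom_spec()].
#' @return List with `ct` (a [scalar_volume()]) and `truth` (lumen mask
#'   filled in).
#' @export
rasterize_phantom <- function(truth, spec = truth$spec) {
  ext <- spec$extents
  n <- prod(ext)
  dmin <- rep(Inf, n); rad <- rep(0, n)
  pad <- ceiling(max(truth$segments$radius) + spec$wall_thickness + 2)
  for (s in seq_len(nrow(truth$segments))) {
    upd <- segment_distance_update(dmin, rad, truth$segments[s, ], ext, pad)
    dmin <- upd$dmin; rad <- upd$rad
  }
  lumen <- dmin <= rad
  wall <- !lumen & dmin <= rad + spec$wall_thickness & is.finite(dmin) & rad > 0
  vol <- rep(spec$parenchyma_hu, n)
  vol[wall] <- spec$wall_hu
  vol[lumen] <- spec$lumen_hu
  if (spec$noise_sd > 0)
    vol <- with_seed(spec$seed + 1L, vol + rnorm(n, 0, spec$noise_sd))
  truth$lumen_mask <- binary_mask(array(lumen, ext), spec$spacing)
  list(ct = scalar_volume(array(vol, ext), spec$spacing), truth = truth)
}

#' Inject leakage blobs into a phantom
#'
#' Paints artifacts onto the volume: the first blob is a capsule bridging
#' the distal ends of two branches with different parents, which forces a
#' cycle (through their common ancestor) in any segmentation that captures
#' it; further blobs are spheres attached to random distal branch
#' surfaces. Artifacts carry the same lumen/wall intensity model as true
#' branches: leakage conduits are admitted by thresholds exactly because
#' their local appearance is airway-like, and only the global tree
#' structure gives them away. Deterministic given `seed`.
#'
#' @param ct The rasterized [scalar_volume()].
#' @param truth The matching `phantom_truth` (lumen mask filled).
#' @param n_blobs Number of artifacts to inject.
#' @param blob_radius Radius range in voxels (the bridging conduit's bulge).
#' @param neck_radius Radius of the bridging conduit at its attachment
#'   points; the conduit tapers from `neck_radius` at the branches to the
#'   sampled bulge radius in the middle, like a flood through a small wall
#'   defect.
#' @param bridge Make the first blob a branch-bridging conduit.
#' @param seed RNG seed.
#' @return List with `ct` (modified volume) and `truth` (leakage mask set).
#' @export
inject_leakage <- function(ct, truth, n_blobs = 1,
                           blob_radius = c(3, 3.25), neck_radius = 1,
                           bridge = TRUE, seed = truth$spec$seed + 2L) {
  if (n_blobs == 0) return(list(ct = ct, truth = truth))
  segs <- truth$segments
  deepest <- segs[segs$generation == max(segs$generation), ]
  if (nrow(deepest) < 2 && bridge)
    stop("no sibling distal branches available for a bridging blob")
  ext <- dim(ct$data)
  paint <- array(FALSE, ext)
  shell <- array(FALSE, ext)
  with_seed(seed, {
    blobs_done <- 0L
    if (bridge) {
      # bridge the closest pair of distal branches with different parents:
      # the resulting cycle closes through their common ancestor, several
      # branch lengths long, so it cannot be mistaken for a voxel-scale seam
      mid <- function(s, t) c(s$x0 + t * (s$x1 - s$x0),
                              s$y0 + t * (s$y1 - s$y0),
                              s$z0 + t * (s$z1 - s$z0))
      # pick the pair whose tip separation is closest to 16 voxels: far
      # enough apart that the enclosed loop cannot be mistaken for (or
      # healed like) a voxel-scale seam, close enough that the conduit is
      # a compact local structure
      pair_sep <- function(a, b)
        sqrt(sum((mid(deepest[a, ], 0.85) - mid(deepest[b, ], 0.85))^2))
      best <- NULL; bestd <- Inf
      for (a in seq_len(nrow(deepest) - 1)) {
        for (b in seq(a + 1, nrow(deepest))) {
          score <- abs(pair_sep(a, b) - 16)
          if (score < bestd) { bestd <- score; best <- c(a, b) }
        }
      }
      p <- mid(deepest[best[1], ], 0.85)
      q <- mid(deepest[best[2], ], 0.85)
      rb <- runif(1, blob_radius[1], blob_radius[2])
      paint <- paint | tapered_capsule_mask(p, q, neck_radius, rb, ext)
      shell <- shell |
        tapered_capsule_mask(p, q, neck_radius + truth$spec$wall_thickness,
                             rb + truth$spec$wall_thickness, ext)
      blobs_done <- 1L
    }
    while (blobs_done < n_blobs) {
      s <- deepest[sample.int(nrow(deepest), 1), ]
      t0 <- runif(1, 0.3, 0.8)
      centre <- c(s$x0 + t0 * (s$x1 - s$x0), s$y0 + t0 * (s$y1 - s$y0),
                  s$z0 + t0 * (s$z1 - s$z0))
      fr <- ortho_frame(c(s$x1 - s$x0, s$y1 - s$y0, s$z1 - s$z0))
      az <- runif(1, 0, 2 * pi)
      rb <- runif(1, blob_radius[1], blob_radius[2])
      centre <- centre + (s$radius + rb * 0.5) *
        (cos(az) * fr$u1 + sin(az) * fr$u2)
      paint <- paint | capsule_mask(centre, centre, rb, ext)
      shell <- shell | capsule_mask(centre, centre,
                                    rb + truth$spec$wall_thickness, ext)
      blobs_done <- blobs_done + 1L
    }
  })
  vol <- ct$data
  wallv <- shell & !paint & !truth$lumen_mask$data & vol < -400
  vol[wallv] <- truth$spec$wall_hu
  vol[paint] <- truth$spec$lumen_hu
  leak <- paint & !truth$lumen_mask$data
  truth$leakage_mask <- binary_mask(leak, ct$spacing)
  list(ct = scalar_volume(vol, ct$spacing, ct$origin), truth = truth)
}

# tapered conduit between p and q: radius interpolates from `neck` at the
# ends to `bulge` at the middle (union of spheres along the segment)
tapered_capsule_mask <- function(p, q, neck, bulge, ext) {
  len <- sqrt(sum((q - p)^2))
  ts <- seq(0, 1, length.out = max(2L, ceiling(len * 2)))
  out <- array(FALSE, ext)
  for (t in ts) {
    r <- neck + (bulge - neck) * sin(pi * t)^2 # volume concentrated mid-span
    c0 <- p + t * (q - p)
    out <- out | capsule_mask(c0, c0, r, ext)
  }
  out
}

# voxels within radius r of the segment p-q (a sphere when p == q)
capsule_mask <- function(p, q, r, ext) {
  lo <- pmax(floor(pmin(p, q) - r) - 1, 1)
  hi <- pmin(ceiling(pmax(p, q) + r) + 1, ext)
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  gx <- rep(xs, times = length(ys) * length(zs))
  gy <- rep(rep(ys, each = length(xs)), times = length(zs))
  gz <- rep(zs, each = length(xs) * length(ys))
  v <- q - p
  L2 <- sum(v^2)
  t <- if (L2 == 0) rep(0, length(gx)) else
    pmin(pmax(((gx - p[1]) * v[1] + (gy - p[2]) * v[2] +
                 (gz - p[3]) * v[3]) / L2, 0), 1)
  d2 <- (gx - (p[1] + t * v[1]))^2 + (gy - (p[2] + t * v[2]))^2 +
    (gz - (p[3] + t * v[3]))^2
  out <- array(FALSE, ext)
  idx <- gx + (gy - 1) * ext[1] + (gz - 1) * ext[1] * ext[2]
  out[idx[d2 <= r^2]] <- TRUE
  out
}

# centerline voxels of one segment, sampled at half-voxel steps
branch_centerline_voxels <- function(seg, ext) {
  p0 <- c(seg$x0, seg$y0, seg$z0); p1 <- c(seg$x1, seg$y1, seg$z1)
  len <- sqrt(sum((p1 - p0)^2))
  ts <- seq(0, 1, length.out = max(2, ceiling(len * 2)))
  pts <- cbind(p0[1] + ts * (p1[1] - p0[1]),
               p0[2] + ts * (p1[2] - p0[2]),
               p0[3] + ts * (p1[3] - p0[3]))
  pts <- round(pts)
  pts <- pts[pts[, 1] >= 1 & pts[, 2] >= 1 & pts[, 3] >= 1 &
               pts[, 1] <= ext[1] & pts[, 2] <= ext[2] & pts[, 3] <= ext[3],
             , drop = FALSE]
  unique(pts[, 1] + (pts[, 2] - 1) * ext[1] + (pts[, 3] - 1) * ext[1] * ext[2])
}

#' EXACT09-style phantom metrics
#'
#' Scores a segmentation against phantom ground truth: a branch counts as
#' detected when at least half of its centerline voxels are inside the
#' segmentation; tree length detected sums the lengths of detected
#' branches; leaks are connected components of the segmentation outside the
#' 1-voxel-dilated truth lumen, and the false positive rate is the fraction
#' of segmented voxels outside that tolerance band.
#'
#' @param seg A [binary_mask()].
#' @param truth A `phantom_truth` with lumen mask.
#' @param spacing Voxel spacing in mm (must match the truth spec).
#' @return List: `branch_count`, `branch_pct`, `tree_length_mm`,
#'   `tree_length_pct`, `leak_count`, `leak_volume_mm3`, `fpr_pct`.
#' @export
exact_metrics <- function(seg, truth, spacing = truth$spec$spacing) {
  if (any(abs(spacing - truth$spec$spacing) > 1e-9) ||
      any(abs(seg$spacing - truth$spec$spacing) > 1e-9))
    stop("spacing mismatch between segmentation and phantom truth")
  ext <- dim(seg$data)
  if (!identical(ext, dim(truth$lumen_mask$data)))
    stop("segmentation grid does not match the phantom")
  segs <- truth$segments
  covered <- vapply(seq_len(nrow(segs)), function(s) {
    cl <- branch_centerline_voxels(segs[s, ], ext)
    mean(seg$data[cl])
  }, numeric(1))
  detected <- covered >= 0.5
  tl <- sum(truth$lengths_mm[detected])
  dil <- array(cpp_dilate1(as.vector(truth$lumen_mask$data), ext), ext)
  outside <- seg$data & !dil
  nseg <- sum(seg$data)
  leaks <- if (any(outside))
    max(cpp_label_components(as.vector(outside), ext, 26L)) else 0L
  list(branch_count = sum(detected),
       branch_pct = 100 * mean(detected),
       tree_length_mm = tl,
       tree_length_pct = 100 * tl / truth$total_length_mm,
       leak_count = leaks,
       leak_volume_mm3 = sum(outside) * prod(spacing),
       fpr_pct = if (nseg == 0) 0 else 100 * sum(outside) / nseg)
}
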