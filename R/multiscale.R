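# Multiresolution scheme: instead of growing the kernel to match bronchi of
# every caliber, the volume is repeatedly down-sampled by max pooling
# (2x2x2 blocks, stride 2) so that main bronchi shrink to the size the fixed
# tubular kernel detects. Each pooled level gets its own appearance map and
# its own globally optimized threshold; level segmentations are combined
# top-down by un-pooling (which on masks acts as an OR with the finer level).

pool_pad <- function(a, fill) {
  d <- dim(a)
  pd <- d + d %% 2L
  if (all(pd == d)) return(a)
  out <- array(fill, pd)
  out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- a
  out
}

#' Max pooling by a factor of 2
#'
#' Non-overlapping 2x2x2 blocks with stride 2; each output voxel is the
#' block maximum and the spacing doubles. Odd extents are padded with the
#' volume minimum (masks with 0) so padding never wins the maximum.
#'
#' @param v A [scalar_volume()] or [binary_mask()].
#' @return Same kind of object with halved (ceiling) extents.
#' @export
max_pool <- function(v) {
  mask <- is_mask(v)
  a <- if (mask) array(as.integer(v$data), dim(v$data)) else v$data
  a <- pool_pad(a, if (mask) 0L else min(a))
  d <- dim(a)
  i1 <- seq(1L, d[1], 2L); i2 <- seq(2L, d[1], 2L)
  j1 <- seq(1L, d[2], 2L); j2 <- seq(2L, d[2], 2L)
  k1 <- seq(1L, d[3], 2L); k2 <- seq(2L, d[3], 2L)
  out <- pmax(a[i1, j1, k1, drop = FALSE], a[i2, j1, k1, drop = FALSE],
              a[i1, j2, k1, drop = FALSE], a[i2, j2, k1, drop = FALSE],
              a[i1, j1, k2, drop = FALSE], a[i2, j1, k2, drop = FALSE],
              a[i1, j2, k2, drop = FALSE], a[i2, j2, k2, drop = FALSE])
  out <- array(out, d %/% 2L)
  if (mask) binary_mask(out > 0, v$spacing * 2, v$origin)
  else scalar_volume(out, v$spacing * 2, v$origin)
}

#' Un-pooling of a mask
#'
#' Broadcasts each coarse voxel to its 2x2x2 block, cropped to
#' `target_shape`. For any mask `M`, `un_pool(max_pool(M))` is a superset of
#' `M` (the OR reading of the max/un-pool pair).
#'
#' @param v A [binary_mask()] at the coarse level.
#' @param target_shape Integer length-3; each extent must be `2 * extent` or
#'   `2 * extent - 1` of the coarse mask.
#' @return A [binary_mask()] of shape `target_shape` at the finer spacing.
#' @export
un_pool <- function(v, target_shape) {
  if (!is_mask(v)) stop("un_pool operates on binary masks")
  d <- dim(v$data)
  target_shape <- as.integer(target_shape)
  if (any(target_shape > 2L * d) || any(target_shape < 2L * d - 1L))
    stop("target_shape incompatible with a 2x un-pooling of ",
         paste(d, collapse = "x"))
  ix <- rep(seq_len(d[1]), each = 2L)[seq_len(target_shape[1])]
  iy <- rep(seq_len(d[2]), each = 2L)[seq_len(target_shape[2])]
  iz <- rep(seq_len(d[3]), each = 2L)[seq_len(target_shape[3])]
  binary_mask(v$data[ix, iy, iz, drop = FALSE], v$spacing / 2, v$origin)
}

# broadcast a coarse scalar map to a finer grid (same index expansion as
# un_pool, for numeric data)
un_pool_scalar <- function(data, target_shape) {
  d <- dim(data)
  ix <- rep(seq_len(d[1]), each = 2L)[seq_len(target_shape[1])]
  iy <- rep(seq_len(d[2]), each = 2L)[seq_len(target_shape[2])]
  iz <- rep(seq_len(d[3]), each = 2L)[seq_len(target_shape[3])]
  data[ix, iy, iz, drop = FALSE]
}

#' Multiscale appearance map
#'
#' Voxelwise maximum of the per-level appearance maps, each un-pooled back
#' to full resolution: a voxel's airway evidence read at whichever caliber
#' the filter matches best. Thick proximal airways respond weakly at full
#' resolution (the very reason for the pooling pyramid), so any per-node
#' appearance comparison -- notably the leakage pruning order -- uses this
#' map rather than the full-resolution map alone.
#'
#' @param level_records The `levels` list returned by
#'   [initial_segmentation()] (each with an `E` appearance map).
#' @return An `appearance_map` at full resolution.
#' @export
multiscale_appearance <- function(level_records) {
  E0 <- level_records[[1]]$E
  out <- E0$data
  for (l in seq_along(level_records)[-1]) {
    up <- level_records[[l]]$E$data
    for (i in seq(l - 1, 1)) {
      target <- dim(level_records[[i]]$E$data)
      up <- un_pool_scalar(up, target)
    }
    out <- pmax(out, up)
  }
  res <- scalar_volume(out, E0$spacing, E0$origin)
  class(res) <- c("appearance_map", class(res))
  res
}

#' Multiresolution initial segmentation
#'
#' Builds the max-pooling pyramid `CT^l`, computes the appearance map `E^l`
#' and a globally optimized threshold `ThOpt^l` at every level, thresholds
#' each level and combines the level segmentations top-down:
#' `Seg^{L,L+1} = Seg^L`, then `Seg^{l-1,l} = Seg^{l-1} OR un_pool(Seg^{l,l+1})`.
#' The result `SegI = Seg^{0,1}` is the initial segmentation; `SegUp^1`
#' (the un-pooled coarse part) is also returned for the distal refinement.
#'
#' @param ct Pre-processed [scalar_volume()].
#' @param levels Number of poolings `L` (default 3).
#' @param search A [threshold_search()] used at every level.
#' @param bank Tubular kernel bank, see [tubular_bank()].
#' @param mask Optional lung [binary_mask()] for the zero-mean shift.
#' @param root_hint Optional voxel (i,j,k) of the trachea entry at full
#'   resolution; scaled per level.
#' @param polarity Passed to [appearance_map()].
#' @return List with `segI`, `segUp1`, `E0` (full-resolution appearance
#'   map) and `levels`, a per-level list of records (`ct`, `E`, `thopt`,
#'   `seg`, plus any optimizer warning).
#' @export
initial_segmentation <- function(ct, levels = 3, search = threshold_search(),
                                 bank = tubular_bank(), mask = NULL,
                                 root_hint = NULL, polarity = "dark") {
  if (levels < 1) stop("levels must be >= 1")
  cts <- vector("list", levels + 1L)
  cts[[1]] <- ct
  msk <- mask
  for (l in seq_len(levels)) {
    cts[[l + 1L]] <- max_pool(cts[[l]])
  }
  recs <- vector("list", levels + 1L)
  for (l in 0:levels) {
    ctl <- cts[[l + 1L]]
    ml <- if (!is.null(msk)) {
      m <- msk
      for (i in seq_len(l)) m <- max_pool(m)
      m
    } else NULL
    E <- appearance_map(ctl, bank, mask = ml, polarity = polarity)
    hint <- if (!is.null(root_hint)) pmax(ceiling(root_hint / 2^l), 1L) else NULL
    th <- tryCatch(
      optimize_threshold(E, search, root_hint = hint),
      error = function(e)
        stop("threshold optimization failed at pyramid level ", l, ": ",
             conditionMessage(e))
    )
    recs[[l + 1L]] <- list(level = l, ct = ctl, E = E, thopt = th$threshold,
                           floor_hit = isTRUE(th$floor),
                           seg = threshold_segment(E, th$threshold))
  }
  # top-down combination
  comb <- recs[[levels + 1L]]$seg               # Seg^{L,L+1} = Seg^L
  segup1 <- NULL
  for (l in levels:1) {
    target <- dim(cts[[l]]$data)
    segup <- un_pool(comb, target)
    if (l == 1L) segup1 <- segup
    fine <- recs[[l]]$seg
    comb <- binary_mask(fine$data | segup$data, fine$spacing, fine$origin)
  }
  list(segI = comb, segUp1 = segup1, E0 = recs[[1]]$E, levels = recs)
}
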