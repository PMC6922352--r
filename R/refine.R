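# Distal refinement. The coarse part of the initial segmentation (SegUp^1,
# everything confirmed at pooled resolution) is trusted; the full-resolution
# remainder SegI \ SegUp^1 splits into connected distal branches. Each
# branch gets its own region of interest -- its Voronoi cell against the
# rest of the segmentation under the Euclidean distance -- and its own
# threshold, optimized on the appearance map restricted to that ROI, so
# locally faint distal airways are rescued without flooding the rest of the
# lung.

#' Distal components of the initial segmentation
#'
#' Connected components (26-connectivity) of `SegI \ SegUp^1`, each the
#' full-resolution tip of one distal branch. Components below `min_voxels`
#' are dropped as speckle.
#'
#' @param segI Initial segmentation [binary_mask()].
#' @param segUp1 Un-pooled coarse segmentation [binary_mask()] (`SegUp^1`).
#' @param min_voxels Minimum component size in voxels.
#' @return List of `distal_component` objects with fields `mask`,
#'   `n_voxels` and `id`.
#' @export
distal_components <- function(segI, segUp1, min_voxels = 2) {
  if (!same_grid(segI, segUp1)) stop("masks must share one grid")
  diffm <- segI$data & !segUp1$data
  if (!any(diffm)) return(list())
  lab <- array(cpp_label_components(as.vector(diffm), dim(diffm), 26L),
               dim(diffm))
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_voxels)
  out <- lapply(seq_along(keep), function(t) {
    cc <- keep[t]
    structure(list(mask = binary_mask(lab == cc, segI$spacing, segI$origin),
                   n_voxels = sizes[cc], id = t),
              class = "distal_component")
  })
  out
}

#' Region of interest of a distal component
#'
#' The Voronoi cell of the component against the rest of the segmentation:
#' `ROI(v) = 1` iff the Euclidean distance (voxel units) from `v` to the
#' component is `<=` its distance to `SegI` minus the component, ties
#' included. If the component is the entire segmentation the ROI is the
#' whole volume (with a warning).
#'
#' @param component A `distal_component` from [distal_components()].
#' @param segI The initial segmentation [binary_mask()].
#' @return A [binary_mask()] containing the component.
#' @export
roi_mask <- function(component, segI) {
  cc <- component$mask
  if (!any(cc$data)) stop("empty distal component")
  rest <- segI$data & !cc$data
  if (!any(rest)) {
    warning("segmentation has a single component; ROI is the whole volume")
    return(binary_mask(array(TRUE, dim(cc$data)), cc$spacing, cc$origin))
  }
  d <- dim(cc$data)
  dcc <- cpp_edt_feature(as.vector(cc$data), d, c(1, 1, 1))$dist
  drest <- cpp_edt_feature(as.vector(rest), d, c(1, 1, 1))$dist
  binary_mask(array(dcc <= drest, d), cc$spacing, cc$origin)
}

# voxel of the component nearest the trusted coarse segmentation: the
# attachment point, used as local graph root
component_root_hint <- function(component, segUp1) {
  d <- dim(component$mask$data)
  if (!any(segUp1$data)) {
    idx <- which(component$mask$data)[1]
    return(as.integer(vox_coords(idx, d)))
  }
  dup <- cpp_edt_feature(as.vector(segUp1$data), d, c(1, 1, 1))$dist
  idx <- which(component$mask$data)
  at <- idx[which.min(dup[idx])]
  as.integer(vox_coords(at, d))
}

#' Refine one distal branch
#'
#' Zeroes the full-resolution appearance map outside the component ROI,
#' optimizes a local threshold on it (graph rooted at the component's
#' attachment point to the coarse segmentation) and returns the local
#' binarization clipped to the ROI. If the bisection bracket fails the
#' component is returned unrefined.
#'
#' @param E0 Full-resolution `appearance_map`.
#' @param component A `distal_component`.
#' @param segI,segUp1 Masks from [initial_segmentation()].
#' @param search A [threshold_search()].
#' @return List with `mask` (refined [binary_mask()]), `threshold` (local
#'   ThOpt or `NA` on fallback), `roi`, and `fallback` flag.
#' @export
refine_branch <- function(E0, component, segI, segUp1,
                          search = threshold_search()) {
  roi <- roi_mask(component, segI)
  hint <- component_root_hint(component, segUp1)
  opt <- tryCatch(
    optimize_threshold(E0, search, roi = roi, root_hint = hint),
    error = function(e) NULL)
  if (is.null(opt)) {
    return(list(mask = component$mask, threshold = NA_real_, roi = roi,
                fallback = TRUE, root_hint = hint))
  }
  masked <- E0$data * roi$data
  refdata <- masked > opt$threshold & roi$data
  if (any(refdata)) {
    # the refined branch is what stays connected to the component being
    # refined; fragments elsewhere in the ROI are not part of this branch
    d <- dim(refdata)
    lab <- array(cpp_label_components(as.vector(refdata), d, 26L), d)
    anchor <- array(cpp_dilate1(as.vector(component$mask$data), d), d)
    keep <- setdiff(unique(lab[anchor & lab > 0]), 0L)
    refdata <- refdata & array(lab %in% keep, d)
  }
  refined <- binary_mask(refdata, E0$spacing, E0$origin)
  if (!any(refined$data)) {
    return(list(mask = component$mask, threshold = opt$threshold, roi = roi,
                fallback = TRUE, root_hint = hint))
  }
  list(mask = refined, threshold = opt$threshold, roi = roi,
       fallback = FALSE, root_hint = hint)
}

#' Refine all distal branches
#'
#' Splits `SegI \ SegUp^1` into distal components, refines each inside its
#' ROI with a locally optimized threshold, and unions the results with the
#' proximal part of the segmentation. Branch order does not matter (set
#' union); the proximal tree is never deleted.
#'
#' @param segI,segUp1 Masks from [initial_segmentation()].
#' @param E0 Full-resolution `appearance_map`.
#' @param search A [threshold_search()].
#' @param min_voxels Minimum distal-component size.
#' @return List with `mask` (the refined segmentation), and `branches`,
#'   the per-component records from [refine_branch()].
#' @export
refine_all <- function(segI, segUp1, E0, search = threshold_search(),
                       min_voxels = 2) {
  comps <- distal_components(segI, segUp1, min_voxels = min_voxels)
  out <- segI$data
  branches <- vector("list", length(comps))
  for (t in seq_along(comps)) {
    br <- refine_branch(E0, comps[[t]], segI, segUp1, search = search)
    branches[[t]] <- br[c("threshold", "fallback", "root_hint")]
    branches[[t]]$n_voxels_in <- comps[[t]]$n_voxels
    branches[[t]]$n_voxels_out <- sum(br$mask$data)
    out <- out | br$mask$data
  }
  list(mask = binary_mask(out, segI$spacing, segI$origin),
       branches = branches)
}
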