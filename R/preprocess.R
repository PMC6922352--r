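# Pre-processing: suppress structures whose interfaces would pollute the
# tubular responses. Lungs are found by Otsu-thresholding the negated
# response to an isotropic Gaussian (air is strongly negative in HU);
# pulmonary vessels by Otsu on the positive part of the maximum response to
# an anisotropic Gaussian bank inside the lungs. Vessels and everything
# outside the lungs are then in-painted with the intensity of the nearest
# lung voxel, so the appearance maps only see lung parenchyma and airways.

otsu_cut <- function(values, bins = 256L) {
  rng <- range(values)
  if (diff(rng) == 0)
    stop("degenerate input: constant response, Otsu threshold undefined")
  scaled <- (values - rng[1]) / diff(rng)
  img <- EBImage::Image(matrix(scaled, ncol = 1L))
  th <- EBImage::otsu(img, range = c(0, 1), levels = bins)
  rng[1] + th * diff(rng)
}

#' Segment the lungs (plus large airways)
#'
#' Convolves the CT with an isotropic Gaussian, applies Otsu thresholding to
#' the negated response, and keeps the filled low-intensity connected
#' components that are larger than 1% of the volume and do not touch the
#' axial image border (which removes the air surrounding the body).
#'
#' @param ct A [scalar_volume()] in HU (air around -1000).
#' @param sigma Isotropic Gaussian scale in voxels (default 2).
#' @param support Odd kernel support.
#' @param min_fraction Minimum component size as a fraction of the volume.
#' @return A [binary_mask()] of the lungs and major airways.
#' @export
segment_lungs <- function(ct, sigma = 2, support = 13, min_fraction = 0.01) {
  kern <- build_gaussian_kernel(rep(sigma, 3), c(0, 0), support)
  resp <- fft_convolve_bank(ct$data, list(kern))[[1]]
  th <- otsu_cut(-resp)
  low <- -resp > th
  if (!any(low))
    stop("degenerate input: no voxels below the Otsu cut")
  lab <- array(cpp_label_components(as.vector(low), dim(low), 6L), dim(low))
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_fraction * length(low))
  # drop components touching the axial (x/y) border: ambient air
  border <- unique(c(lab[c(1, dim(lab)[1]), , ], lab[, c(1, dim(lab)[2]), ]))
  keep <- setdiff(keep, border[border > 0])
  if (length(keep) == 0L)
    stop("degenerate input: no interior low-intensity component found")
  mask <- array(lab %in% keep, dim(lab))
  mask <- fill_holes(mask)
  binary_mask(mask, ct$spacing, ct$origin)
}

# fill cavities: background components not connected to the volume border
fill_holes <- function(mask) {
  bg <- !mask
  lab <- array(cpp_label_components(as.vector(bg), dim(bg), 6L), dim(bg))
  d <- dim(mask)
  border_labels <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ],
                            lab[, , c(1, d[3])]))
  border_labels <- border_labels[border_labels > 0]
  mask | (lab > 0 & !(lab %in% border_labels))
}

#' Segment pulmonary vessels
#'
#' Otsu threshold on the voxelwise maximum over orientations of the positive
#' part of anisotropic Gaussian responses, restricted to the lung mask.
#' Bright elongated structures (contrast-filled vessels) respond strongly.
#'
#' @param ct A [scalar_volume()] in HU.
#' @param lungs Lung [binary_mask()] from [segment_lungs()].
#' @param sigma Anisotropic scales in voxels, long axis last.
#' @param orientations Orientation list, defaults to the appearance-bank grid.
#' @param support Odd kernel support.
#' @return A [binary_mask()] of vessels inside the lungs.
#' @export
segment_vessels <- function(ct, lungs, sigma = c(1, 1, 4),
                            orientations = orientation_bank(),
                            support = 21) {
  if (!same_grid(ct, lungs)) stop("lung mask grid does not match the volume")
  if (!(sigma[3] > sigma[1])) stop("vessel bank must be anisotropic")
  bank <- lapply(orientations, function(tp)
    build_gaussian_kernel(sigma, tp, support))
  responses <- fft_convolve_bank(ct$data - mean(ct$data[lungs$data]), bank)
  mx <- responses[[1]]
  if (length(responses) > 1L)
    for (r in responses[-1L]) mx <- pmax(mx, r)
  mx[mx < 0] <- 0
  inside <- lungs$data & mx > 0
  if (!any(inside))
    return(binary_mask(array(FALSE, dim(ct$data)), ct$spacing, ct$origin))
  vals <- mx[lungs$data]
  th <- tryCatch(otsu_cut(vals), error = function(e) Inf)
  binary_mask(lungs$data & mx > th, ct$spacing, ct$origin)
}

#' In-paint masked voxels with their nearest neighbour
#'
#' Every voxel under the mask receives the intensity of its nearest
#' (Euclidean, voxel units) voxel outside the mask; all other voxels are
#' unchanged. Used to replace vessels and extra-pulmonary tissue with
#' parenchyma-like intensities before filtering.
#'
#' @param ct A [scalar_volume()].
#' @param mask A [binary_mask()] of voxels to replace.
#' @return A [scalar_volume()] with masked voxels filled.
#' @export
inpaint <- function(ct, mask) {
  if (!same_grid(ct, mask)) stop("mask shape must equal the volume shape")
  if (!any(mask$data)) return(ct)
  donors <- !mask$data
  if (!any(donors)) stop("mask covers the whole volume: no donor voxels")
  ft <- cpp_edt_feature(as.vector(donors), dim(ct$data), c(1, 1, 1))
  out <- ct$data
  idx <- which(mask$data)
  out[idx] <- ct$data[ft$index[idx]]
  scalar_volume(out, ct$spacing, ct$origin)
}

#' Full CT pre-processing
#'
#' Segments lungs and vessels, then in-paints vessels together with all
#' tissue outside the lungs (filler values come from the nearest lung
#' voxel). Returns the in-painted volume and both masks.
#'
#' @param ct A [scalar_volume()] in HU.
#' @param lung_sigma,vessel_sigma Gaussian scales in voxels.
#' @param orientations Orientations for the vessel bank.
#' @return List with `ct` (in-painted), `lungs`, `vessels`.
#' @export
preprocess_ct <- function(ct, lung_sigma = 2, vessel_sigma = c(1, 1, 4),
                          orientations = orientation_bank()) {
  lungs <- segment_lungs(ct, sigma = lung_sigma)
  vessels <- segment_vessels(ct, lungs, sigma = vessel_sigma,
                             orientations = orientations)
  paint <- binary_mask(!lungs$data | vessels$data, ct$spacing, ct$origin)
  list(ct = inpaint(ct, paint), lungs = lungs, vessels = vessels)
}
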