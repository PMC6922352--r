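# Appearance maps: the voxelwise maximum over orientations of the CT volume
# convolved with the tubular kernel bank. Convolution is linear (zero-padded)
# and computed by FFT; the volume is shifted to zero mean (inside the lung
# mask when one is given) beforehand, which both suppresses spurious border
# responses and makes the map exactly invariant to global intensity shifts.

# smallest 5-smooth integer >= n, for fast mixed-radix FFTs
next_fast_size <- function(n) {
  while (TRUE) {
    m <- n
    for (p in c(2, 3, 5)) while (m %% p == 0) m <- m / p
    if (m == 1) return(n)
    n <- n + 1
  }
}

# Linear "same size" convolution of a 3D array with kernels sharing one
# support, via a single forward FFT of the padded volume. Returns a list of
# response arrays aligned with `vol`.
fft_convolve_bank <- function(vol, kernels) {
  dv <- dim(vol)
  dk <- dim(kernels[[1]]$weights)
  half <- (dk - 1L) %/% 2L
  pd <- vapply(dv + dk - 1L, next_fast_size, numeric(1))
  pad <- array(0, pd)
  pad[seq_len(dv[1]), seq_len(dv[2]), seq_len(dv[3])] <- vol
  FV <- fft(pad)
  npad <- prod(pd)
  lapply(kernels, function(kern) {
    kw <- kern$weights
    kp <- array(0, pd)
    # centre the kernel at the padded origin with wrap-around so that the
    # output at (i,j,k) is the response centred on voxel (i,j,k)
    ix <- c(seq(half[1] + 1L, dk[1]), seq_len(half[1]))
    wx <- c(seq_len(dk[1] - half[1]), seq(pd[1] - half[1] + 1L, pd[1]))
    iy <- c(seq(half[2] + 1L, dk[2]), seq_len(half[2]))
    wy <- c(seq_len(dk[2] - half[2]), seq(pd[2] - half[2] + 1L, pd[2]))
    iz <- c(seq(half[3] + 1L, dk[3]), seq_len(half[3]))
    wz <- c(seq_len(dk[3] - half[3]), seq(pd[3] - half[3] + 1L, pd[3]))
    kp[wx, wy, wz] <- kw[ix, iy, iz]
    resp <- Re(fft(FV * fft(kp), inverse = TRUE)) / npad
    array(resp[seq_len(dv[1]), seq_len(dv[2]), seq_len(dv[3])], dv)
  })
}

#' Airway appearance map
#'
#' Computes `E(i,j,k) = max over orientations of (ct * psi)(i,j,k)`, the
#' voxelwise maximum response to a bank of oriented tubular kernels. High
#' values mark voxels whose neighbourhood looks like an airway lumen: a dark
#' tube on a brighter background (set `polarity = "bright"` for bright
#' tubes). Responses are in units of the unit-L2 kernels applied to the
#' (mean-shifted) input intensities.
#'
#' @param ct A [scalar_volume()] (CT in HU after pre-processing, or a pooled
#'   level of the pyramid).
#' @param bank List of tubular `oriented_kernel`s sharing one `sigma`, e.g.
#'   from [tubular_bank()].
#' @param mask Optional [binary_mask()]; the mean used for the zero-mean
#'   shift is computed inside it (typically the lung mask).
#' @param polarity `"dark"` (airway lumina, default) or `"bright"`.
#' @return An `appearance_map` (a [scalar_volume()] subclass) with the bank
#'   orientation count and scale recorded as attributes.
#' @export
appearance_map <- function(ct, bank, mask = NULL,
                           polarity = c("dark", "bright")) {
  polarity <- match.arg(polarity)
  if (length(bank) == 0L) stop("empty kernel bank")
  if (!all(vapply(bank, function(k) identical(k$kind, "tubular"), logical(1))))
    stop("appearance maps require tubular kernels")
  v <- ct$data
  mu <- if (!is.null(mask)) {
    if (!same_grid(ct, mask)) stop("mask grid does not match the volume")
    if (!any(mask$data)) mean(v) else mean(v[mask$data])
  } else mean(v)
  v <- v - mu
  if (polarity == "bright") v <- -v
  responses <- fft_convolve_bank(v, bank)
  E <- responses[[1]]
  if (length(responses) > 1L)
    for (r in responses[-1L]) E <- pmax(E, r)
  out <- scalar_volume(E, ct$spacing, ct$origin)
  class(out) <- c("appearance_map", class(out))
  attr(out, "sigma") <- bank[[1]]$sigma
  attr(out, "n_orientations") <- length(bank)
  out
}

#' Threshold an appearance map
#'
#' The elementary binarization of the pipeline: `mask = 1` exactly where
#' `E > th` (strict inequality). Antitone in `th`: raising the threshold can
#' only shrink the segmentation.
#'
#' @param E An `appearance_map` (or any [scalar_volume()]).
#' @param th Scalar threshold in appearance units.
#' @return A [binary_mask()] on the same grid.
#' @export
threshold_segment <- function(E, th) {
  binary_mask(E$data > th, E$spacing, E$origin)
}
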