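# Oriented filter kernels. The tubular detector is an anisotropic
# Laplacian-of-Gaussian with sigma_z >> sigma_x = sigma_y, evaluated in a
# rotated frame whose z-axis is the tube direction eta, then cropped along
# that axis so the kernel support is consistent with a tube of finite
# elongation, re-centred to zero integral and scaled to unit L2 norm.
# Rotation is applied analytically inside the kernel formula (coordinates are
# rotated, never the sampled array), which avoids resampling artifacts.

#' Direction vector of an orientation
#'
#' Converts an orientation `(theta, phi)` to the unit vector
#' `eta = (cos(phi)cos(theta), cos(phi)sin(theta), sin(phi))`.
#'
#' @param theta_phi Numeric length-2, azimuth and elevation in radians.
#' @return Unit 3-vector.
#' @export
orientation_eta <- function(theta_phi) {
  th <- theta_phi[1]; ph <- theta_phi[2]
  c(cos(ph) * cos(th), cos(ph) * sin(th), sin(ph))
}

# Orthonormal frame (u, v, eta): rows map grid coordinates to the rotated
# frame in which the Gaussian is axis-aligned with z along eta.
rotation_frame <- function(theta_phi) {
  th <- theta_phi[1]; ph <- theta_phi[2]
  eta <- orientation_eta(theta_phi)
  u1 <- c(-sin(th), cos(th), 0)                      # ytilde axis
  u2 <- c(-sin(ph) * cos(th), -sin(ph) * sin(th), cos(ph)) # xtilde axis
  rbind(xt = u2, yt = u1, zt = eta)
}

kernel_grid <- function(support) {
  if (length(support) == 1L) support <- rep(support, 3L)
  if (any(support %% 2 == 0))
    stop("kernel support extents must be odd so the kernel has a centre voxel")
  h <- (support - 1L) / 2L
  list(x = rep(-h[1]:h[1], times = support[2] * support[3]),
       y = rep(rep(-h[2]:h[2], each = support[1]), times = support[3]),
       z = rep(-h[3]:h[3], each = support[1] * support[2]),
       support = support)
}

#' Oriented anisotropic Gaussian kernel
#'
#' Discrete oriented 3D Gaussian with scales `sigma` (voxels) along the
#' rotated axes and long axis along `eta(theta_phi)`, renormalized to unit
#' sum (the analytic normalization constant does not sum to 1 on a truncated
#' grid).
#'
#' @param sigma Numeric length-3, `(sigma_x, sigma_y, sigma_z)` in voxels.
#' @param theta_phi Orientation `(theta, phi)` in radians.
#' @param support Odd kernel extents in voxels (scalar or length-3).
#' @return An `oriented_kernel` with `kind = "gaussian"`.
#' @export
build_gaussian_kernel <- function(sigma, theta_phi = c(0, 0), support = 13) {
  if (any(sigma <= 0)) stop("sigma components must be strictly positive")
  gr <- kernel_grid(support)
  R <- rotation_frame(theta_phi)
  xt <- R[1, 1] * gr$x + R[1, 2] * gr$y + R[1, 3] * gr$z
  yt <- R[2, 1] * gr$x + R[2, 2] * gr$y + R[2, 3] * gr$z
  zt <- R[3, 1] * gr$x + R[3, 2] * gr$y + R[3, 3] * gr$z
  g <- exp(-(xt^2 / (2 * sigma[1]^2) + yt^2 / (2 * sigma[2]^2) +
               zt^2 / (2 * sigma[3]^2))) / ((2 * pi)^1.5 * prod(sigma))
  g <- g / sum(g)
  structure(list(weights = array(g, gr$support), sigma = sigma,
                 theta_phi = theta_phi, eta = orientation_eta(theta_phi),
                 crop_extent = NA_real_, kind = "gaussian"),
            class = "oriented_kernel")
}

#' Cropped tubular (anisotropic Laplacian-of-Gaussian) kernel
#'
#' Builds the oriented airway detector: the Laplacian of the anisotropic
#' Gaussian with `sigma_z > sigma_y = sigma_x`, cropped along its long axis
#' at `|z| <= floor(z_crop)` where `z_crop = qnorm(0.99) * sigma_z` (the 0.01
#' tail point of the 1D profile along the tube), then re-centred to zero sum
#' and scaled to unit L2 norm, in that order. With this sign convention a
#' dark lumen on a brighter background yields a positive response.
#'
#' @inheritParams build_gaussian_kernel
#' @param support Odd kernel extents in voxels; must contain the crop extent.
#' @return An `oriented_kernel` with `kind = "tubular"`, carrying the crop
#'   half-extent in voxels as `crop_extent`.
#' @export
build_tubular_kernel <- function(sigma, theta_phi = c(0, 0), support = 33) {
  if (!(sigma[3] > sigma[1]) || sigma[1] != sigma[2])
    stop("tubular kernel requires sigma_z > sigma_y = sigma_x")
  zcrop <- floor(qnorm(0.99) * sigma[3])
  if (length(support) == 1L) support <- rep(support, 3L)
  if (min((support - 1) / 2) < zcrop)
    stop("kernel support too small to contain the crop extent ", zcrop)
  gr <- kernel_grid(support)
  R <- rotation_frame(theta_phi)
  xt <- R[1, 1] * gr$x + R[1, 2] * gr$y + R[1, 3] * gr$z
  yt <- R[2, 1] * gr$x + R[2, 2] * gr$y + R[2, 3] * gr$z
  zt <- R[3, 1] * gr$x + R[3, 2] * gr$y + R[3, 3] * gr$z
  g <- exp(-(xt^2 / (2 * sigma[1]^2) + yt^2 / (2 * sigma[2]^2) +
               zt^2 / (2 * sigma[3]^2))) / ((2 * pi)^1.5 * prod(sigma))
  lap <- (xt^2 / sigma[1]^4 + yt^2 / sigma[2]^4 + zt^2 / sigma[3]^4) * g -
    (1 / sigma[1]^2 + 1 / sigma[2]^2 + 1 / sigma[3]^2) * g
  keep <- abs(zt) <= zcrop
  w <- ifelse(keep, lap, 0)
  w[keep] <- w[keep] - mean(w[keep])   # zero integral over surviving support
  w <- w / sqrt(sum(w^2))              # unit L2 norm
  structure(list(weights = array(w, gr$support), sigma = sigma,
                 theta_phi = theta_phi, eta = orientation_eta(theta_phi),
                 crop_extent = zcrop, kind = "tubular"),
            class = "oriented_kernel")
}

#' @export
print.oriented_kernel <- function(x, ...) {
  cat(sprintf("<oriented_kernel> %s, sigma (%s), theta %.3f phi %.3f, support %s\n",
              x$kind, paste(x$sigma, collapse = ","),
              x$theta_phi[1], x$theta_phi[2],
              paste(dim(x$weights), collapse = "x")))
  invisible(x)
}

#' Hemisphere orientation bank
#'
#' Regular `(theta, phi)` grid with angular step `step` (default `pi/6`).
#' Tube symmetry makes `theta` and `theta + pi` equivalent, so azimuths span
#' half a turn; the poles `phi = +/- pi/2` are emitted once each and
#' duplicate directions are removed.
#'
#' @param step Angular step in radians; must divide `pi`.
#' @return A list of `(theta, phi)` orientation pairs.
#' @export
orientation_bank <- function(step = pi / 6) {
  n <- pi / step
  if (abs(n - round(n)) > 1e-9) stop("orientation step must divide pi")
  n <- round(n)
  thetas <- (seq_len(n) - 1) * step
  m <- floor((pi / 2) / step + 1e-9)
  phis <- (-m:m) * step
  out <- list()
  seen <- character()
  for (ph in phis) {
    ths <- if (abs(abs(ph) - pi / 2) < 1e-9) 0 else thetas # poles degenerate
    for (th in ths) {
      eta <- orientation_eta(c(th, ph))
      key <- paste(round(eta, 9), collapse = "|")
      if (key %in% seen) next
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- c(theta = th, phi = ph)
    }
  }
  out
}

#' Bank of tubular kernels over a set of orientations
#'
#' @param sigma Scales in voxels, see [build_tubular_kernel()].
#' @param orientations List of `(theta, phi)` pairs, e.g. from
#'   [orientation_bank()].
#' @param support Odd kernel extents.
#' @return List of `oriented_kernel` objects.
#' @export
tubular_bank <- function(sigma = c(1, 1, 4), orientations = orientation_bank(),
                         support = 33) {
  lapply(orientations, function(tp)
    build_tubular_kernel(sigma, tp, support = support))
}
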