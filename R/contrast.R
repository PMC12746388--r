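#' Estimate the shared background phase from the two passes
#'
#' The positive- and negative-pass images are `x+ = e^{i phi} x` and
#' `x- = e^{i phi} x*`, so their voxelwise product is `e^{2 i phi} |x|^2`:
#' the tissue phase cancels and half the product's angle recovers phi on
#' the principal half-angle branch (-pi/2, pi/2]. Voxels whose product
#' magnitude falls below `floor_frac` times the maximum are masked (phi set
#' to 0 there) and counted.
#'
#' @param x_plus,x_minus Complex arrays of identical shape.
#' @param floor_frac Relative magnitude floor for masking. Default 1e-8.
#' @return A `phase_map` with elements `phi`, `shape`, `mask` (TRUE where
#'   estimated) and `n_masked`.
#' @export
estimate_background_phase <- function(x_plus, x_minus, floor_frac = 1e-8) {
  stopifnot(identical(dim(x_plus), dim(x_minus)))
  p <- x_plus * x_minus
  ok <- Mod(p) > floor_frac * max(Mod(p))
  phi <- array(0, dim = dim(p))
  phi[ok] <- Arg(p[ok]) / 2
  structure(list(phi = phi, shape = as.integer(dim(p)), mask = ok,
                 n_masked = sum(!ok)),
            class = "phase_map")
}

#' Combine positive and negative passes into a multi-contrast image
#'
#' Averages the phase-corrected positive pass with the conjugated
#' phase-corrected negative pass:
#' `x = (x+ e^{-i phi} + (x- e^{-i phi})*) / 2`. With exact inputs this is
#' the true multi-contrast image up to a per-voxel sign tied to the
#' half-angle branch of the phase estimate; contrast extraction is
#' invariant to that sign.
#'
#' @param x_plus,x_minus Complex arrays of identical shape.
#' @param phase A `phase_map` (estimated or ground truth).
#' @return An object of class `mc_image`: list with complex `x`, `shape`
#'   and the `phase` used.
#' @export
combine_passes <- function(x_plus, x_minus, phase) {
  stopifnot(identical(dim(x_plus), dim(x_minus)),
            inherits(phase, "phase_map"),
            identical(as.integer(dim(x_plus)), as.integer(phase$shape)))
  e <- exp(-1i * phase$phi)
  x <- 0.5 * (x_plus * e + Conj(x_minus * e))
  structure(list(x = x, shape = as.integer(dim(x)), phase = phase),
            class = "mc_image")
}

#' @export
print.mc_image <- function(x, ...) {
  cat(sprintf("mc_image: %s complex volume, peak |x| = %.4g\n",
              paste(x$shape, collapse = "x"), max(Mod(x$x))))
  invisible(x)
}

#' Extract a soft-tissue contrast at phase modulation psi
#'
#' Rotates the complex multi-contrast image by `psi` and takes the absolute
#' value of the real part: `x_psi = |Re(x e^{i psi})|`. The result is
#' pi-periodic in psi, so psi is reduced modulo 180 degrees; the
#' absolute value also makes the extraction invariant to the half-angle
#' sign ambiguity of the background-phase estimate.
#'
#' @param x An `mc_image`, or a bare complex array.
#' @param psi Phase modulation in degrees (any finite value).
#' @return An `extracted_contrast`: list with real non-negative `image`,
#'   the reduced `psi` and `shape`.
#' @export
extract_contrast <- function(x, psi) {
  stopifnot(is.numeric(psi), length(psi) == 1L, is.finite(psi))
  arr <- if (inherits(x, "mc_image")) x$x else x
  psi <- psi %% 180
  img <- abs(Re(arr * exp(1i * psi * pi / 180)))
  structure(list(image = img, psi = psi, shape = as.integer(dim(arr))),
            class = "extracted_contrast")
}

#' @export
print.extracted_contrast <- function(x, ...) {
  cat(sprintf("extracted_contrast: psi = %.4g deg, %s volume, max %.4g\n",
              x$psi, paste(x$shape, collapse = "x"), max(x$image)))
  invisible(x)
}
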