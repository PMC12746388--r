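#' Reconstruction configuration
#'
#' @param lambda Joint-L0 wavelet threshold in absolute signal units
#'   (>= 0; 0 disables regularization). See [lambda_heuristic()] for the
#'   documented default scaling.
#' @param n_outer Outer alternating iterations (data consistency +
#'   threshold). Default 10.
#' @param n_inner Conjugate-gradient iterations per data-consistency
#'   update. Default 5.
#' @param wavelet_levels Decomposition levels of the periodic Daubechies
#'   transform. Default 3.
#' @return A `recon_config` object.
#' @export
recon_config <- function(lambda = 0, n_outer = 10L, n_inner = 5L,
                         wavelet_levels = 3L) {
  stopifnot(lambda >= 0, n_outer >= 1L, n_inner >= 1L, wavelet_levels >= 1L)
  structure(list(lambda = lambda, n_outer = as.integer(n_outer),
                 n_inner = as.integer(n_inner),
                 wavelet_levels = as.integer(wavelet_levels)),
            class = "recon_config")
}

## CG on the normal equations A^H A x = A^H y (CGNR), warm-startable.
## Returns list(x, resid = per-iteration data residuals ||Ax - y||).
cg_normal <- function(y, coils, plan, n_iters, x0 = NULL, rtol = 0) {
  b <- encode_adjoint(y, coils, plan)
  x <- if (is.null(x0)) array(0 + 0i, dim = plan$shape) else x0
  normal <- function(u) encode_adjoint(encode_forward(u, coils, plan),
                                       coils, plan)
  r <- b - normal(x)
  p <- r
  rs <- sum(Mod(r)^2)
  resid <- numeric(0)
  diverged <- FALSE
  data_res <- function(u) sqrt(sum(Mod(encode_forward(u, coils, plan) - y)^2))
  for (it in seq_len(n_iters)) {
    Ap <- normal(p)
    denom <- Re(sum(Conj(p) * Ap))
    if (denom <= 0) break
    alpha <- rs / denom
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs_new <- sum(Mod(r)^2)
    resid <- c(resid, data_res(x))
    if (length(resid) > 1L &&
        resid[length(resid)] > resid[length(resid) - 1L] * (1 + 1e-8))
      diverged <- TRUE
    if (rtol > 0 && sqrt(rs_new) <= rtol * sqrt(sum(Mod(b)^2))) {
      p <- r; rs <- rs_new
      break
    }
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  if (diverged)
    warning("conjugate gradient data residual increased; solution flagged",
            call. = FALSE)
  list(x = x, resid = resid, diverged = diverged)
}

#' Least-squares image reconstruction (CG-SENSE)
#'
#' Solves `argmin_u || F S u - y ||^2` by conjugate gradients on the normal
#' equations. The data-consistency residual is non-increasing per
#' iteration; an increase is flagged with a warning.
#'
#' @param y Complex sample matrix (samples x coils) for a single dataset.
#' @param coils A [make_coil_maps()] object.
#' @param plan A [nufft_plan()] for the acquisition trajectory.
#' @param n_iters Number of CG iterations. Default 15.
#' @param x0 Optional warm start image.
#' @return Complex image array with attribute `"resid"` (the per-iteration
#'   data residual trace) and `"diverged"`.
#' @export
reconstruct_least_squares <- function(y, coils, plan, n_iters = 15L,
                                      x0 = NULL) {
  y <- as.matrix(y)
  stopifnot(nrow(y) == plan$m, ncol(y) == coils$n_coils)
  fit <- cg_normal(y, coils, plan, n_iters, x0 = x0)
  structure(fit$x, resid = fit$resid, diverged = fit$diverged)
}

#' Joint hard threshold across a multi-contrast coefficient stack
#'
#' For each coefficient location the root-sum-of-squares across all images
#' is compared with `lambda`: below the threshold every image's coefficient
#' is zeroed, otherwise all are retained unchanged. All images therefore
#' share one wavelet support.
#'
#' @param coefs List of coefficient arrays of identical shape (one per
#'   image; complex allowed).
#' @param lambda Non-negative threshold in coefficient units.
#' @return List of thresholded coefficient arrays.
#' @export
joint_hard_threshold <- function(coefs, lambda) {
  stopifnot(is.list(coefs), length(coefs) >= 1L, lambda >= 0)
  if (lambda == 0) return(coefs)
  rss <- sqrt(Reduce(`+`, lapply(coefs, function(c) Mod(c)^2)))
  keep <- rss >= lambda
  lapply(coefs, function(c) c * keep)
}

#' Density-compensated gridding preview reconstruction
#'
#' Adjoint encoding with radial density-compensation weights, amplitude-
#' calibrated against a smooth reference object so the preview is in image
#' units. Used for quick looks and the [lambda_heuristic()] scaling, never
#' inside the iterative reconstructions.
#'
#' @param y Complex sample matrix (samples x coils).
#' @param coils A [make_coil_maps()] object.
#' @param plan A [nufft_plan()].
#' @param traj The matching radial `trajectory`.
#' @return Complex image array.
#' @export
gridding_preview <- function(y, coils, plan, traj) {
  stopifnot(traj$mode == "radial_golden")
  w <- density_weights(traj)
  ## calibrate amplitude on a smooth Gaussian blob
  ax <- lapply(plan$shape, function(n)
    seq(-1, 1, length.out = n + 1L)[-1L] - 1 / n)
  g2 <- if (plan$ndim == 2L) outer(ax[[1]]^2, ax[[2]]^2, `+`)
  else outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  ref <- exp(-g2 / 0.18) + 0i
  back <- encode_adjoint(encode_forward(ref, coils, plan), coils, plan,
                         weights = w)
  s <- Re(sum(Conj(back) * ref)) / sum(Mod(back)^2)
  s * encode_adjoint(as.matrix(y), coils, plan, weights = w)
}

#' Default joint-L0 threshold heuristic
#'
#' A fraction of the maximum coefficient root-sum-of-squares of the
#' amplitude-calibrated gridding preview images — an acquisition-scaled
#' default for [reconstruct_joint()].
#'
#' @param y4 Named list of four sample matrices (`ute_pos`, `ute_neg`,
#'   `cte_pos`, `cte_neg`).
#' @param coils,plan As in [reconstruct_joint()].
#' @param traj The radial trajectory (for density weights); NULL uses the
#'   plain adjoint (Cartesian).
#' @param frac Fraction of the maximum coefficient RSS. Default 0.001: at the scale of noise-only coefficients, a conservative value that denoises without biting into structure.
#' @param wavelet_levels Decomposition levels. Default 3.
#' @return A non-negative scalar threshold.
#' @export
lambda_heuristic <- function(y4, coils, plan, traj = NULL, frac = 0.001,
                             wavelet_levels = 3L) {
  coefs <- lapply(y4, function(y) {
    img <- if (!is.null(traj) && traj$mode == "radial_golden")
      gridding_preview(y, coils, plan, traj)
    else encode_adjoint(as.matrix(y), coils, plan) / prod(plan$shape)
    dwt_periodic(img, levels = wavelet_levels)
  })
  rss <- sqrt(Reduce(`+`, lapply(coefs, function(c) Mod(c)^2)))
  frac * max(rss)
}

#' Joint reconstruction of the four dual-echo, dual-pass datasets
#'
#' Alternates warm-started conjugate-gradient data-consistency updates on
#' each of the four k-space datasets with a joint-L0 wavelet proximal step
#' (shared support across echoes and passes). With `lambda = 0` and one
#' outer iteration this reduces exactly to four independent least-squares
#' reconstructions. The scheme runs a fixed iteration budget; the L0
#' penalty is nonconvex and carries no convergence guarantee.
#'
#' @param y4 Named list of four complex sample matrices (`ute_pos`,
#'   `ute_neg`, `cte_pos`, `cte_neg`), sharing trajectory and coils.
#' @param coils A [make_coil_maps()] object.
#' @param plan A [nufft_plan()].
#' @param cfg A [recon_config()].
#' @return An `mc_stack` (named list of four complex image arrays) with
#'   attribute `"resid"` (final per-dataset data residuals).
#' @export
reconstruct_joint <- function(y4, coils, plan, cfg = recon_config()) {
  stopifnot(is.list(y4),
            all(c("ute_pos", "ute_neg", "cte_pos", "cte_neg") %in% names(y4)))
  keys <- c("ute_pos", "ute_neg", "cte_pos", "cte_neg")
  y4 <- lapply(y4[keys], as.matrix)
  u <- stats::setNames(rep(list(array(0 + 0i, dim = plan$shape)), 4L), keys)
  resid <- stats::setNames(numeric(4L), keys)
  for (outer in seq_len(cfg$n_outer)) {
    for (k in keys) {
      fit <- cg_normal(y4[[k]], coils, plan, cfg$n_inner, x0 = u[[k]])
      u[[k]] <- fit$x
      resid[k] <- if (length(fit$resid)) fit$resid[length(fit$resid)] else NA
    }
    if (cfg$lambda > 0) {
      coefs <- lapply(u, dwt_periodic, levels = cfg$wavelet_levels)
      coefs <- joint_hard_threshold(coefs, cfg$lambda)
      u <- lapply(coefs, idwt_periodic, levels = cfg$wavelet_levels)
    }
  }
  structure(u, class = "mc_stack", resid = resid, shape = plan$shape)
}

#' Normalized root-mean-square error
#'
#' @param x Estimate (numeric or complex array).
#' @param ref Reference of the same shape.
#' @param mask Optional logical array restricting the evaluation.
#' @return `||x - ref|| / ||ref||` over the (masked) voxels.
#' @export
nrmse <- function(x, ref, mask = NULL) {
  stopifnot(identical(dim(x), dim(ref)))
  if (!is.null(mask)) {
    x <- x[mask]; ref <- ref[mask]
  }
  sqrt(sum(Mod(x - ref)^2) / sum(Mod(ref)^2))
}
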