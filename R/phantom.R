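#' Default tissue classes for the head-like digital phantom
#'
#' Relaxation times and proton densities representative of a 3 T head exam:
#' air (pd = 0), subcutaneous fat, cortical bone water (T2 0.3-0.4 ms, pd
#' about 0.2), white matter, gray matter and CSF.
#'
#' @return Named list of [tissue_params()], in class-id order starting with
#'   `air` (id 1).
#' @export
default_tissue_classes <- function() {
  list(
    air  = tissue_params(t1 = 1000, t2 = 1000, pd = 0,    label = "air"),
    fat  = tissue_params(t1 = 370,  t2 = 90,   pd = 1.0,  label = "fat"),
    bone = tissue_params(t1 = 240,  t2 = 0.35, pd = 0.2,  label = "bone"),
    wm   = tissue_params(t1 = 850,  t2 = 70,   pd = 0.7,  label = "wm"),
    gm   = tissue_params(t1 = 1300, t2 = 100,  pd = 0.8,  label = "gm"),
    csf  = tissue_params(t1 = 4000, t2 = 2000, pd = 1.0,  label = "csf")
  )
}

#' Generate a head-like digital phantom
#'
#' Builds a deterministic, seeded concentric phantom: an outer fat ring, a
#' bone (skull) shell, a thin subarachnoid CSF layer, a gray-matter cortex,
#' a white-matter core and two CSF ventricle pockets; air outside. In 3D the
#' same construction uses confocal ellipsoids. The seed applies a small
#' jitter to the shell semi-axes so different seeds give distinct geometry
#' while the map remains a pure function of (shape, seed).
#'
#' @param shape Integer vector of length 2 or 3 (grid size per dimension,
#'   each >= 32).
#' @param seed Integer RNG seed.
#' @param spacing Isotropic voxel spacing in mm (metadata only). Default 1.
#' @param classes Named list of [tissue_params()]; first class must be air.
#' @return An object of class `tissue_map`: list with `class_id` (integer
#'   array), `classes`, `labels`, `shape`, `spacing`, `seed`.
#' @export
make_phantom <- function(shape = c(64L, 64L), seed = 1L, spacing = 1,
                         classes = default_tissue_classes()) {
  shape <- as.integer(shape)
  if (!(length(shape) %in% c(2L, 3L))) stop("shape must be 2D or 3D")
  if (any(shape < 32L)) stop("each dimension must be >= 32")
  stopifnot(identical(names(classes)[1], "air"),
            classes$air$pd == 0)

  jit <- local({
    set.seed(as.integer(seed))
    runif(4L, -0.02, 0.02)
  })

  ax <- lapply(seq_along(shape), function(d)
    seq(-1, 1, length.out = shape[d] + 1L)[-1L] - 1 / shape[d])
  if (length(shape) == 2L) {
    X <- matrix(ax[[1]], shape[1], shape[2])
    Y <- matrix(ax[[2]], shape[1], shape[2], byrow = TRUE)
    Z <- 0
  } else {
    X <- array(ax[[1]], shape)
    Y <- aperm(array(ax[[2]], shape[c(2, 1, 3)]), c(2, 1, 3))
    Z <- aperm(array(ax[[3]], shape[c(3, 1, 2)]), c(2, 3, 1))
  }

  ell <- function(a, b, cz = 0.9, x0 = 0, y0 = 0)
    ((X - x0) / a)^2 + ((Y - y0) / b)^2 +
      (if (length(shape) == 3L) (Z / cz)^2 else 0) <= 1

  a0 <- 0.92 + jit[1]; b0 <- 0.78 + jit[2]        # outer scalp
  sk <- 0.10                                       # scalp/fat thickness
  bt <- 0.11 + jit[3] * 0.5                        # bone shell thickness
  ct <- 0.05                                       # subarachnoid CSF layer
  gt <- 0.16 + jit[4] * 0.5                        # cortical GM thickness

  id <- array(1L, dim = shape)                     # air
  id[ell(a0, b0)] <- 2L                            # fat
  id[ell(a0 - sk, b0 - sk, 0.82)] <- 3L            # bone shell
  id[ell(a0 - sk - bt, b0 - sk - bt, 0.72)] <- 6L  # CSF layer
  id[ell(a0 - sk - bt - ct, b0 - sk - bt - ct, 0.66)] <- 5L  # GM cortex
  id[ell(a0 - sk - bt - ct - gt, b0 - sk - bt - ct - gt, 0.55)] <- 4L  # WM
  ## ventricles: two CSF pockets inside the WM core
  id[ell(0.10, 0.22, 0.35, x0 = -0.16, y0 = 0.02)] <- 6L
  id[ell(0.10, 0.22, 0.35, x0 = 0.16, y0 = 0.02)] <- 6L

  structure(list(class_id = id, classes = classes,
                 labels = names(classes), shape = shape,
                 spacing = spacing, seed = as.integer(seed)),
            class = "tissue_map")
}

#' @export
print.tissue_map <- function(x, ...) {
  cat(sprintf("tissue_map: %s grid, %d classes (seed %d)\n",
              paste(x$shape, collapse = "x"), length(x$classes), x$seed))
  print(round(class_fractions(x), 4))
  invisible(x)
}

#' Voxel fraction of each tissue class
#' @param tmap A `tissue_map`.
#' @return Named numeric vector of voxel fractions.
#' @export
class_fractions <- function(tmap) {
  stopifnot(inherits(tmap, "tissue_map"))
  f <- tabulate(tmap$class_id, nbins = length(tmap$classes)) /
    length(tmap$class_id)
  names(f) <- tmap$labels
  f
}

#' Proton-density map of a phantom
#' @param tmap A `tissue_map`.
#' @return Numeric array of per-voxel proton density (0 in air).
#' @export
proton_density_map <- function(tmap) {
  stopifnot(inherits(tmap, "tissue_map"))
  pd <- vapply(tmap$classes, `[[`, numeric(1), "pd")
  array(pd[tmap$class_id], dim = tmap$shape)
}

## smooth unit-variance random field: white noise low-passed by a Gaussian
## kernel in k-space (fraction `cutoff` of the grid Nyquist)
smooth_random_field <- function(shape, cutoff = 0.08) {
  w <- array(stats::rnorm(prod(shape)), dim = shape)
  ax <- lapply(shape, function(n) {
    f <- (seq_len(n) - 1) / n
    pmin(f, 1 - f)                       # cycles/sample in [0, 0.5]
  })
  if (length(shape) == 2L) {
    f2 <- outer(ax[[1]]^2, ax[[2]]^2, `+`)
  } else {
    f2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  }
  filt <- exp(-f2 / (2 * cutoff^2))
  sm <- Re(stats::fft(stats::fft(w) * filt, inverse = TRUE)) / prod(shape)
  sm / stats::sd(sm)
}

#' Smooth spatially varying background phase
#'
#' Models the nuisance phase from static-field and RF inhomogeneity as a
#' low-order polynomial plus a smooth seeded random field, scaled so the
#' maximum absolute phase equals `amplitude`. The same map is shared by the
#' positive and negative passes (the model's central assumption).
#'
#' @param shape Integer vector, grid size (2D or 3D).
#' @param amplitude Maximum absolute phase in radians (>= 0). Values below
#'   pi/2 keep the half-angle estimate on the principal branch everywhere.
#' @param seed Integer RNG seed.
#' @return An object of class `phase_map`: list with `phi` (radians) and
#'   `shape`.
#' @export
make_background_phase <- function(shape, amplitude = pi / 3, seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) %in% c(2L, 3L), amplitude >= 0)
  if (amplitude == 0)
    return(structure(list(phi = array(0, dim = shape), shape = shape),
                     class = "phase_map"))
  set.seed(as.integer(seed))
  ax <- lapply(shape, function(n)
    seq(-1, 1, length.out = n + 1L)[-1L] - 1 / n)
  if (length(shape) == 2L) {
    X <- matrix(ax[[1]], shape[1], shape[2])
    Y <- matrix(ax[[2]], shape[1], shape[2], byrow = TRUE)
    Zc <- 0
  } else {
    X <- array(ax[[1]], shape)
    Y <- aperm(array(ax[[2]], shape[c(2, 1, 3)]), c(2, 1, 3))
    Zc <- aperm(array(ax[[3]], shape[c(3, 1, 2)]), c(2, 3, 1))
  }
  cf <- stats::runif(6L, -1, 1)
  poly <- cf[1] * X + cf[2] * Y + cf[3] * X * Y + cf[4] * (X^2 - 0.5) +
    cf[5] * (Y^2 - 0.5) + (if (length(shape) == 3L) cf[6] * Zc else 0)
  phi <- poly + 0.5 * smooth_random_field(shape)
  phi <- phi * (amplitude / max(abs(phi)))
  structure(list(phi = phi, shape = shape), class = "phase_map")
}

#' Synthetic smooth complex coil sensitivity maps
#'
#' Gaussian-lobe sensitivities centered on a ring just outside the FOV with
#' a gentle per-coil linear phase; deterministic given the seed. With
#' `mode = "uniform"` a single all-ones coil is returned.
#'
#' @param shape Integer vector, grid size (2D or 3D).
#' @param n_coils Number of coils (>= 1).
#' @param seed Integer RNG seed.
#' @param mode `"gaussian"` (default) or `"uniform"`.
#' @return An object of class `coil_maps`: list with `maps` (complex array
#'   of dim `c(shape, n_coils)`), `n_coils`, `shape`.
#' @export
make_coil_maps <- function(shape, n_coils = 6L, seed = 1L,
                           mode = c("gaussian", "uniform")) {
  shape <- as.integer(shape)
  stopifnot(length(shape) %in% c(2L, 3L))
  n_coils <- as.integer(n_coils)
  if (n_coils < 1L) stop("n_coils must be >= 1")
  mode <- match.arg(mode)
  maps <- array(0 + 0i, dim = c(shape, n_coils))
  if (mode == "uniform") {
    maps[] <- 1 + 0i
  } else {
    set.seed(as.integer(seed))
    ang0 <- stats::runif(1L, 0, 2 * pi)
    tilt <- matrix(stats::runif(3L * n_coils, -0.6, 0.6), ncol = 3L)
    ax <- lapply(shape, function(n)
      seq(-1, 1, length.out = n + 1L)[-1L] - 1 / n)
    if (length(shape) == 2L) {
      X <- matrix(ax[[1]], shape[1], shape[2])
      Y <- matrix(ax[[2]], shape[1], shape[2], byrow = TRUE)
      Zc <- array(0, dim = shape)
    } else {
      X <- array(ax[[1]], shape)
      Y <- aperm(array(ax[[2]], shape[c(2, 1, 3)]), c(2, 1, 3))
      Zc <- aperm(array(ax[[3]], shape[c(3, 1, 2)]), c(2, 3, 1))
    }
    idx_all <- slice.index(maps, length(shape) + 1L)
    for (cc in seq_len(n_coils)) {
      ang <- ang0 + 2 * pi * (cc - 1) / n_coils
      cx <- 1.25 * cos(ang); cy <- 1.25 * sin(ang)
      mag <- exp(-((X - cx)^2 + (Y - cy)^2 + Zc^2) / (2 * 0.85^2))
      ph <- tilt[cc, 1] * X + tilt[cc, 2] * Y +
        (if (length(shape) == 3L) tilt[cc, 3] * Zc else 0) +
        2 * pi * (cc - 1) / n_coils
      maps[idx_all == cc] <- mag * exp(1i * ph)
    }
  }
  structure(list(maps = maps, n_coils = n_coils, shape = shape, mode = mode),
            class = "coil_maps")
}

#' Root-sum-of-squares of coil sensitivities
#' @param coils A `coil_maps` object.
#' @return Real array over the grid.
#' @export
coil_rss <- function(coils) {
  stopifnot(inherits(coils, "coil_maps"))
  nd <- length(coils$shape)
  sqrt(apply(abs(coils$maps)^2, seq_len(nd), sum))
}

#' Ideal voxelwise dual-echo, dual-pass images
#'
#' Computes the per-class steady-state signal at both echoes for the given
#' sequence (positive RF phase increment), broadcasts it over the phantom,
#' and applies the shared background phase: the positive pass is
#' `exp(i phi) * x_k` and the negative pass `exp(i phi) * Conj(x_k)` for
#' each echo k. Air voxels are exactly zero.
#'
#' @param tmap A [make_phantom()] tissue map.
#' @param seq A [seq_params()] with `theta > 0`.
#' @param phase A [make_background_phase()] map (or NULL for zero phase).
#' @param method Simulation path, `"epg"` (default) or `"isochromat"`.
#' @return An object of class `mc_stack`: named list of four complex arrays
#'   `ute_pos`, `ute_neg`, `cte_pos`, `cte_neg`, with the noiseless
#'   uncorrupted per-echo truth in attributes `truth_ute`, `truth_cte` and
#'   the per-class signals in attribute `signals`.
#' @export
synthesize_ideal_images <- function(tmap, seq, phase = NULL,
                                    method = c("epg", "isochromat")) {
  stopifnot(inherits(tmap, "tissue_map"), inherits(seq, "seq_params"))
  if (seq$theta <= 0)
    stop("ideal image synthesis expects a positive RF phase increment")
  method <- match.arg(method)
  simfun <- if (method == "epg") simulate_steady_state_epg
  else simulate_steady_state_isochromat
  sig <- lapply(tmap$classes, function(ts) simfun(seq, ts))
  s_ute <- vapply(sig, `[[`, complex(1), "s_ute")
  s_cte <- vapply(sig, `[[`, complex(1), "s_cte")
  x_ute <- array(s_ute[tmap$class_id], dim = tmap$shape)
  x_cte <- array(s_cte[tmap$class_id], dim = tmap$shape)
  ph <- if (is.null(phase)) array(0, dim = tmap$shape) else {
    stopifnot(inherits(phase, "phase_map"),
              identical(as.integer(phase$shape), tmap$shape))
    phase$phi
  }
  e <- exp(1i * ph)
  out <- list(ute_pos = e * x_ute, ute_neg = e * Conj(x_ute),
              cte_pos = e * x_cte, cte_neg = e * Conj(x_cte))
  structure(out, class = "mc_stack",
            truth_ute = x_ute, truth_cte = x_cte,
            phase = ph, signals = sig, shape = tmap$shape)
}

#' @export
print.mc_stack <- function(x, ...) {
  cat(sprintf("mc_stack: 4 complex volumes (%s), peak |x| = %.4g\n",
              paste(dim(x$ute_pos), collapse = "x"),
              max(vapply(x[c("ute_pos", "ute_neg", "cte_pos", "cte_neg")],
                         function(v) max(abs(v)), numeric(1)))))
  invisible(x)
}
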