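#' Bundle the four acquired k-space datasets with their geometry
#'
#' @param samples Named list of four complex sample matrices (samples x
#'   coils): `ute_pos`, `ute_neg`, `cte_pos`, `cte_neg`.
#' @param traj The shared `trajectory`.
#' @param coils The shared [make_coil_maps()] object.
#' @param meta List of acquisition metadata (sequence parameters, seeds,
#'   noise level, ...).
#' @return A `kspace_data` object.
#' @export
kspace_data <- function(samples, traj, coils, meta = list()) {
  keys <- c("ute_pos", "ute_neg", "cte_pos", "cte_neg")
  stopifnot(is.list(samples), all(keys %in% names(samples)),
            inherits(traj, "trajectory"), inherits(coils, "coil_maps"))
  samples <- lapply(samples[keys], as.matrix)
  m <- nrow(traj$coords)
  for (k in keys) {
    if (nrow(samples[[k]]) != m)
      stop(sprintf("dataset '%s' has %d samples but trajectory has %d",
                   k, nrow(samples[[k]]), m))
    if (ncol(samples[[k]]) != coils$n_coils)
      stop(sprintf("dataset '%s' has %d coils but coil maps have %d",
                   k, ncol(samples[[k]]), coils$n_coils))
  }
  structure(list(samples = samples, trajectory = traj, coil_maps = coils,
                 meta = meta),
            class = "kspace_data")
}

#' @export
print.kspace_data <- function(x, ...) {
  cat(sprintf("kspace_data: 4 datasets, %d samples x %d coils (%s)\n",
              nrow(x$samples$ute_pos), ncol(x$samples$ute_pos),
              x$trajectory$mode))
  invisible(x)
}

write_complex_bin <- function(z, path) {
  v <- as.vector(z)
  writeBin(as.double(rbind(Re(v), Im(v))), path, size = 8L,
           endian = "little")
}

read_complex_bin <- function(path, n) {
  raw <- readBin(path, "double", n = 2L * n, size = 8L, endian = "little")
  if (length(raw) != 2L * n)
    stop(sprintf("dataset '%s' truncated: expected %d doubles, got %d",
                 basename(path), 2L * n, length(raw)))
  complex(real = raw[c(TRUE, FALSE)], imaginary = raw[c(FALSE, TRUE)])
}

#' Write a k-space bundle to a self-describing directory container
#'
#' The container holds named datasets `samples` (complex, interleaved
#' real/imag doubles, little-endian, column-major over sample x coil x
#' dataset), `trajectory` (doubles, sample x dimension), `coil_maps`
#' (complex over grid x coil) and `meta` (JSON with every shape, name and
#' acquisition parameter). Round-trips are bit-exact.
#'
#' @param ks A [kspace_data()] object.
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_kspace_bundle <- function(ks, dir) {
  stopifnot(inherits(ks, "kspace_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  keys <- names(ks$samples)
  tr <- ks$trajectory
  cm <- ks$coil_maps
  meta <- list(
    format = "psgre-kspace-bundle-v1",
    datasets = keys,
    n_samples = nrow(ks$samples[[1]]),
    n_coils = ncol(ks$samples[[1]]),
    grid_shape = cm$shape,
    trajectory = list(mode = tr$mode, ndim = tr$ndim,
                      n_spokes = tr$n_spokes, n_spoke_samples = tr$n_samples,
                      ramp_fraction = tr$ramp_fraction),
    meta = ks$meta
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write_complex_bin(do.call(cbind, ks$samples), file.path(dir, "samples"))
  writeBin(as.double(as.vector(tr$coords)), file.path(dir, "trajectory"),
           size = 8L, endian = "little")
  write_complex_bin(cm$maps, file.path(dir, "coil_maps"))
  invisible(dir)
}

#' Read a k-space bundle written by [write_kspace_bundle()]
#'
#' @param dir Container directory.
#' @return A [kspace_data()] object, bit-identical to the one written.
#' @export
read_kspace_bundle <- function(dir) {
  need <- c("meta.json", "samples", "trajectory", "coil_maps")
  for (f in need)
    if (!file.exists(file.path(dir, f)))
      stop(sprintf("k-space bundle is missing dataset '%s'", f))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  if (!identical(meta$format, "psgre-kspace-bundle-v1"))
    stop("dataset 'meta.json' does not describe a psgre k-space bundle")
  m <- meta$n_samples; nc <- meta$n_coils
  keys <- meta$datasets
  all_s <- read_complex_bin(file.path(dir, "samples"),
                            m * nc * length(keys))
  samples <- lapply(seq_along(keys), function(i)
    matrix(all_s[((i - 1) * m * nc + 1):(i * m * nc)], m, nc))
  names(samples) <- keys

  tmeta <- meta$trajectory
  ncoord <- file.size(file.path(dir, "trajectory")) / 8L
  coords <- matrix(readBin(file.path(dir, "trajectory"), "double",
                           n = ncoord, size = 8L, endian = "little"),
                   ncol = tmeta$ndim)
  if (tmeta$mode == "radial_golden") {
    traj <- golden_angle_radial_trajectory(tmeta$n_spokes,
                                           tmeta$n_spoke_samples,
                                           tmeta$ramp_fraction, tmeta$ndim)
  } else {
    traj <- cartesian_trajectory(meta$grid_shape)
  }
  traj$coords <- coords

  shape <- as.integer(meta$grid_shape)
  maps <- array(read_complex_bin(file.path(dir, "coil_maps"),
                                 prod(shape) * nc),
                dim = c(shape, nc))
  coils <- structure(list(maps = maps, n_coils = nc, shape = shape,
                          mode = "loaded"),
                     class = "coil_maps")
  kspace_data(samples, traj, coils, meta$meta)
}

#' Write a complex volume as a NIfTI real/imaginary pair
#'
#' The complex image is stored in one NIfTI file with a trailing dimension
#' of size 2 holding the real and imaginary parts (in that order), in
#' double precision.
#'
#' @param x Complex array (2D or 3D).
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_complex_nifti <- function(x, path) {
  arr <- array(c(Re(x), Im(x)), dim = c(dim(x), 2L))
  RNifti::writeNifti(arr, path, datatype = "double")
  invisible(path)
}

#' Read a complex volume written by [write_complex_nifti()]
#' @param path NIfTI path.
#' @return Complex array.
#' @export
read_complex_nifti <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  nd <- length(dim(arr))
  if (dim(arr)[nd] != 2L)
    stop("not a real/imaginary pair NIfTI: trailing dimension must be 2")
  idx <- lapply(dim(arr)[-nd], seq_len)
  re <- do.call(`[`, c(list(arr), idx, list(1L)))
  im <- do.call(`[`, c(list(arr), idx, list(2L)))
  array(complex(real = re, imaginary = im), dim = dim(arr)[-nd])
}

#' Write a real volume as NIfTI (double precision)
#' @param x Real array.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_real_nifti <- function(x, path) {
  RNifti::writeNifti(array(as.double(x), dim = dim(x)), path,
                     datatype = "double")
  invisible(path)
}
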