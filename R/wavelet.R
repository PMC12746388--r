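## Orthonormal 4-tap Daubechies (D4) analysis filter
daub4_filters <- function() {
  s3 <- sqrt(3)
  h <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
  g <- rev(h) * c(1, -1, 1, -1)        # quadrature mirror
  list(h = h, g = g)
}

## one-level periodic analysis matrix for even length n:
## rows 1..n/2 approx, rows n/2+1..n detail (orthonormal)
dwt_step_matrix <- function(n) {
  stopifnot(n %% 2L == 0L, n >= 4L)
  f <- daub4_filters()
  W <- matrix(0, n, n)
  for (i in seq_len(n / 2)) {
    cols <- ((2 * (i - 1) + seq_len(4L) - 1) %% n) + 1L
    for (k in 1:4) {
      W[i, cols[k]] <- W[i, cols[k]] + f$h[k]
      W[i + n / 2, cols[k]] <- W[i + n / 2, cols[k]] + f$g[k]
    }
  }
  W
}

dwt_matrix_cache <- new.env(parent = emptyenv())
dwt_matrix <- function(n) {
  key <- as.character(n)
  if (is.null(dwt_matrix_cache[[key]]))
    dwt_matrix_cache[[key]] <- dwt_step_matrix(n)
  dwt_matrix_cache[[key]]
}

apply_along <- function(a, d, M) {
  ## multiply M (n x n) along dimension d of array a
  dm <- dim(a)
  perm <- c(d, setdiff(seq_along(dm), d))
  ap <- aperm(a, perm)
  dim(ap) <- c(dm[d], prod(dm[-d]))
  ap <- M %*% ap
  dim(ap) <- dm[perm]
  aperm(ap, order(perm))
}

#' Multi-level periodic Daubechies wavelet transform
#'
#' Separable orthonormal 4-tap Daubechies decomposition with periodic
#' boundaries; the approximation block is recursively transformed `levels`
#' times. Coefficients are returned in an array of the input's shape
#' (pyramid layout, approximation in the low corner). Being orthonormal,
#' the transform preserves the L2 norm exactly.
#'
#' @param x Real or complex array (2D or 3D); every dimension must be
#'   divisible by `2^levels`.
#' @param levels Number of decomposition levels. Default 3.
#' @return Coefficient array of the same shape, with attribute `"levels"`.
#' @export
dwt_periodic <- function(x, levels = 3L) {
  dm <- dim(x)
  stopifnot(length(dm) %in% c(2L, 3L), levels >= 1L)
  if (any(dm %% 2L^levels != 0L))
    stop("array dimensions must be divisible by 2^levels")
  out <- x
  n <- dm
  for (l in seq_len(levels)) {
    blk <- lapply(n, seq_len)
    sub <- do.call(`[`, c(list(out), blk, list(drop = FALSE)))
    for (d in seq_along(n)) sub <- apply_along(sub, d, dwt_matrix(n[d]))
    out <- do.call(`[<-`, c(list(out), blk, list(sub)))
    n <- n %/% 2L
  }
  attr(out, "levels") <- as.integer(levels)
  out
}

#' Inverse of [dwt_periodic()]
#' @param w Coefficient array from [dwt_periodic()].
#' @param levels Number of levels (defaults to the array's `"levels"`
#'   attribute).
#' @return Reconstructed array.
#' @export
idwt_periodic <- function(w, levels = attr(w, "levels")) {
  dm <- dim(w)
  stopifnot(length(dm) %in% c(2L, 3L), !is.null(levels))
  out <- w
  for (l in rev(seq_len(levels))) {
    n <- dm %/% 2L^(l - 1L)
    blk <- lapply(n, seq_len)
    sub <- do.call(`[`, c(list(out), blk, list(drop = FALSE)))
    for (d in seq_along(n)) sub <- apply_along(sub, d, t(dwt_matrix(n[d])))
    out <- do.call(`[<-`, c(list(out), blk, list(sub)))
  }
  attr(out, "levels") <- NULL
  out
}
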