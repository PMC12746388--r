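## shared fixtures, computed lazily and cached for the whole test run

.fix <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fix[[name]])) .fix[[name]] <- force(expr)
  .fix[[name]]
}

## steady-state simulation, warnings about slow CSF-like convergence muffled
quiet_epg <- function(seq, tissue, ...)
  suppressWarnings(simulate_steady_state_epg(seq, tissue, ...))
quiet_iso <- function(seq, tissue, ...)
  suppressWarnings(simulate_steady_state_isochromat(seq, tissue, ...))

default_phantom <- function()
  fixture("phantom64", make_phantom(c(64L, 64L), seed = 1L))

default_ideal <- function()
  fixture("ideal64", suppressWarnings(
    synthesize_ideal_images(default_phantom(), seq_params(),
                            make_background_phase(c(64L, 64L), pi / 3,
                                                  seed = 3L))))

default_coils <- function()
  fixture("coils64", make_coil_maps(c(64L, 64L), 4L, seed = 5L))

random_complex <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  complex(real = rnorm(n), imaginary = rnorm(n))
}

## brute-force discrete Fourier transform oracle at arbitrary coordinates
ndft_oracle <- function(image, coords) {
  dm <- dim(image)
  ax <- lapply(dm, function(n) seq_len(n) - 1 - floor(n / 2))
  vapply(seq_len(nrow(coords)), function(j) {
    ph <- outer(ax[[1]] * coords[j, 1], ax[[2]] * coords[j, 2], `+`)
    if (length(dm) == 3L)
      ph <- outer(ph, ax[[3]] * coords[j, 3], `+`)
    sum(image * exp(-2i * pi * ph))
  }, complex(1))
}
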