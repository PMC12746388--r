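Package: psgre
Title: Dual-Pass Dual-Echo Partially RF-Spoiled Gradient-Echo MRI
    Simulation and Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Bloch-level steady-state simulation and model-based image
    reconstruction for simultaneous bone-selective, T1-weighted and
    T2-weighted imaging with a dual-pass, dual-echo, partially RF-spoiled
    gradient-echo acquisition. Provides isochromat and extended-phase-graph
    simulators for arbitrary quadratic RF phase schedules, seeded head-like
    digital phantoms with smooth coil maps and background phase,
    golden-angle center-out radial and Cartesian encoding operators with a
    Kaiser-Bessel gridding non-uniform Fourier transform, conjugate-gradient
    and jointly L0-wavelet-regularized reconstruction of the four acquired
    datasets, background-phase estimation and pass combination, retrospective
    soft-tissue contrast extraction by phase modulation, and bone-selective
    imaging by direct and weighted-least-squares normalized echo subtraction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
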