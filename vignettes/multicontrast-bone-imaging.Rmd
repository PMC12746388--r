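---
title: "Simultaneous bone-selective and multi-contrast soft-tissue MRI: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simultaneous bone-selective and multi-contrast soft-tissue MRI: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psgre)
```

## The signal model

A gradient-echo train with repetition time TR and flip angle alpha reaches a
steady state whose character is set by the RF phase schedule
phi(n) = phi(n-1) + n * theta, i.e. phi(n) = phi(0) + theta n(n+1)/2. Three
regimes matter:

* **theta = 117 deg** approximates ideal spoiling: the residual transverse
  magnetization adds incoherently and the magnitude approaches the Ernst
  amplitude `PD sin(a)(1 - E1) / (1 - E1 cos(a))`, `E1 = exp(-TR/T1)`. The
  signal is essentially purely T1-weighted.
* **theta = 0** is a coherent (unbalanced SSFP) train, weighting by both T1
  and T2.
* **small theta (1-4 deg)** — *partial* RF spoiling — leaves just enough
  coherence that tissues with longer T2 accumulate a larger steady-state
  signal *phase*. For T2 >> TR the phase is a strictly monotone function of
  T2, while the magnitude retains T1 weighting. The complex steady-state
  image therefore carries T1 and T2 information along different directions
  of the complex plane; we call it the multi-contrast image `x`.

A soft-tissue contrast is *extracted* retrospectively by rotating `x` by a
phase modulation `psi` and projecting on the real axis:

    x_psi = | Re( x e^{i psi} ) |

The absolute value makes `x_psi` pi-periodic in `psi` (rotating by 180 deg
just negates the projection), so every encodable contrast lives in
`psi` in `[0, 180)` degrees. Scanning `psi` at 1-degree steps and asking for
strict magnitude orderings across a tissue set yields the T1-weighted
interval (magnitude decreasing in T1) and the T2-weighted interval
(increasing in T2); `weighting_intervals()` implements exactly this scan.
The absolute position of these intervals depends on the receiver phase
convention (see below) and is therefore reported by the package itself
rather than assumed.

### Background phase and the two-pass scheme

Real acquisitions multiply `x` by a smooth nuisance phase `e^{i phi(r)}`
from static-field and transmit inhomogeneity, which would scramble the
extraction. The remedy is a second pass with the *sign of theta flipped*,
whose uncorrupted image is the conjugate `x*`:

    x_+ = e^{i phi(r)} x        (positive pass)
    x_- = e^{i phi(r)} x*       (negative pass)

The voxelwise product `x_+ x_- = e^{2 i phi(r)} |x|^2` cancels the tissue
phase; half its angle recovers `phi(r)` on the principal branch
(-pi/2, pi/2], and the multi-contrast image is retrieved by averaging the
phase-corrected passes, `x = (x_+ e^{-i phi} + (x_- e^{-i phi})*) / 2`,
which also halves independent noise variance. Note the *product* (not a
conjugated product) is the algebraically consistent form: conjugating the
negative pass would cancel the background phase instead of the tissue
phase. A voxel phase outside the principal branch flips the sign of the
combined voxel; the absolute value in the extraction makes all downstream
results invariant to that branch ambiguity, which is why the package
defines `x_psi` with the magnitude.

The model assumes the background phase is identical in both passes; the
generator enforces this, and `estimate_background_phase()` is applied per
echo so an echo-dependent phase could be accommodated.

### Dual-echo bone imaging

Collagen-bound bone water (T2 about 0.3-0.4 ms, proton density about 20%)
decays almost completely within a TR, so its steady state is independent of
the phase schedule: a small theta can be used for soft-tissue encoding
without affecting bone contrast. Two echoes per TR — an ultrashort echo
(UTE, 80 us) that still sees bone and a conventional echo (CTE, 2.38 ms)
that does not — give the normalized echo subtraction

    x_s = (|x_UTE| - |x_CTE|) / (|x_UTE| + |x_CTE|)

For noiseless mono-exponential decay at zero off-resonance this equals
`tanh(dTE / (2 T2))` exactly, for *any* theta and flip angle: proton
density cancels in the ratio. With dTE = 2.3 ms this is 0.995 for bone
(T2 = 0.38 ms) and 0.014 for white-matter-like T2 = 80 ms — a bright-bone,
dark-soft-tissue image. Magnitudes are used in the ratio (the background
phase then drops out); the complex difference magnitude is used only to
build the weights below.

Air voxels make the direct ratio a 0/0 noise amplifier. The weighted
least-squares variant solves

    argmin_u || W^(1/2) ( (|x_UTE|+|x_CTE|) u - (|x_UTE|-|x_CTE|) ) ||^2

by conjugate gradients from zero, where `W` is a Hanning-smoothed copy of
the plain echo subtraction. The system is voxelwise-diagonal, so CG acts as
a spectral filter: voxels with large `W (|x_UTE|+|x_CTE|)^2` converge to
the direct ratio within a few iterations while air voxels (W near 0) stay
at the zero initialization. *Early termination is the mechanism*, not an
economy: the default of 10 iterations keeps air near zero at machine level
while bone reaches about 96% of its direct-ratio value on the default
phantom.

### Acquisition and reconstruction

Each pass acquires both echoes along a golden-angle (111.246 deg
increment), center-out radial trajectory whose radial position grows
quadratically during the gradient ramp (40 of 64 samples per spoke at the
default 160 us ramp / 4 us dwell geometry is the clinical analogue; the
package default uses a 0.2 ramp fraction) and linearly thereafter. Golden-
angle sets are nested, so retrospective scan-time reduction is literally
spoke truncation. In 3D the spoke directions follow the two-angle
generalized golden means on the sphere, which preserves the nesting
property.

The four datasets (2 echoes x 2 passes) are reconstructed jointly:

    argmin_{u_kl} sum_kl || F S u_kl - y_kl ||^2 + R(u_k,l)

where `R` is a joint-L0 wavelet penalty: at each coefficient location the
root-sum-of-squares over the four images is compared with a threshold
lambda; below it all four are zeroed, above it all four are kept. All
images share one wavelet support, which protects thin bone present mainly
in the UTE images. The solver alternates warm-started CG data-consistency
updates with this joint hard threshold for a fixed iteration budget
(default 8 outer x 4 inner); the L0 penalty is nonconvex and no convergence
guarantee is claimed — with lambda = 0 and one outer iteration the scheme
*is* plain CG, which is also the unit-test anchor.

## Numerical choices

* **Simulators.** Two independent formalisms are provided. The isochromat
  path propagates an ensemble (default 256 spins) whose spoiler-induced
  intravoxel phases are uniformly spaced over 2 pi per TR — the ideal
  unbalanced-gradient model — with exact per-TR rotation and relaxation.
  The extended-phase-graph (EPG) path propagates configuration states with
  the standard RF mixing matrix and a one-cycle shift per TR (default cap
  600 orders, adaptively tightened when high orders are negligible). They
  agree to better than 1e-3 relative over the tested theta/T1/T2 grid, and
  the EPG path is the default everywhere for speed.
* **Receiver convention.** The receiver is demodulated by the phase of the
  acquiring pulse plus 90 degrees, so an ideally spoiled FID lands on the
  positive real axis. This makes theta -> -theta conjugate the signal
  exactly — the property the two-pass scheme relies on. RF pulses are
  instantaneous; excitation-efficiency loss for short-T2 species is out of
  scope, as is off-resonance (fixed at zero; echoes then see pure T2
  decay, so `s_CTE / s_UTE = exp(-dTE/T2)` exactly).
* **Steady state.** Declared when the demodulated signal changes by less
  than 1e-8 (relative) between TRs, or at 5000 pulses, whichever is first.
  CSF-like T1 (4 s) cannot meet 1e-8 within 5000 TRs at TR = 5.5 ms; the
  simulator returns the last value with a warning, and the residual
  transient (order 1e-3) is far below any tolerance used downstream.
* **Imperfect spoiling is real physics.** At T2 >> TR the 117-degree
  quadratic schedule is *not* exactly ideal spoiling: the converged
  magnitude sits several percent (8.3% at T1 = 1000 ms, T2 = 80 ms) below
  the Ernst amplitude, and the steady-state phase retains a small,
  non-monotonic ripple across T2 (0.38 rad over T2 in [10, 2000] ms,
  unchanged from 5000 to 60000 pulses). Both are reproduced identically by
  the two independent simulators. Diffusion, which damps high-order
  coherences on real scanners, is deliberately not modeled. The package
  therefore states the 117-degree claims in the form the physics supports:
  exact Ernst agreement in the short-T2 regime (where spoiling is ideal by
  decay), a bounded deviation at long T2, and phase "flatness" declared as
  one third of the small-theta encoding range on the same grid together
  with non-monotonicity — flat in the sense of not encoding T2.
* **NUFFT.** Kaiser-Bessel gridding with oversampling 2.0 and kernel width
  8 (Beatty beta), implemented as a precomputed sparse interpolation matrix
  over the oversampled FFT grid with an analytic separable apodization and
  a delta-calibrated constant. Forward accuracy is about 1e-7 relative
  against the direct discrete transform; the adjoint is the exact
  conjugate transpose by construction. Cartesian-full plans bypass
  gridding and use the exact FFT. Coordinates are cycles/pixel in
  [-0.5, 0.5) with the image centered at `floor(N/2) + 1`.
* **Wavelets.** Orthonormal 4-tap Daubechies filters, periodic boundary,
  3 decomposition levels (grid sizes must be divisible by 8). Orthonormality
  means the threshold lambda lives in image units.
* **lambda default.** `lambda_heuristic()` sets lambda to a fraction
  (default 0.001) of the maximum coefficient root-sum-of-squares of an
  amplitude-calibrated gridding preview. This is deliberately conservative
  — at the scale of noise-only coefficients. On 4x-undersampled noisy data
  it consistently improves (never worsens) the reconstruction error across
  phantom geometries; larger fractions (0.005-0.01) can help more on some
  geometries but hurt on others by biting into true structure, so they are
  left to the user.
* **Density compensation** (|k|^(d-1) midpoint weights adjusted for ramp
  sampling) is used only for preview/heuristic purposes, never inside the
  iterative reconstructions.
* **Bone epsilon.** The direct ratio floors its denominator at 1e-6 of the
  peak UTE magnitude; flagged voxels are returned as zero.

## The synthetic-data generator as study conditions

`make_phantom()` builds a concentric head-like section: outer fat ring,
cortical bone shell (T2 0.35 ms, T1 240 ms, PD 0.2), a thin subarachnoid
CSF layer, gray-matter cortex, white-matter core and two CSF ventricles,
air outside (PD exactly 0). Relaxation values are standard 3 T literature
numbers (WM 850/70 ms, GM 1300/100 ms, CSF 4000/2000 ms, fat 370/90 ms).
The seed jitters the shell geometry slightly so phantoms are distinct but
fully reproducible; the bone shell occupies roughly 12% of the default
64x64 grid. Coil sensitivities are Gaussian lobes on a ring outside the
FOV with gentle linear phases (default 6 coils); the background phase is a
seeded low-order polynomial plus a smoothed random field scaled to a
pi/3 maximum — inside the principal half-angle branch.

Noise is i.i.d. complex Gaussian per k-space sample with sigma =
peak-signal / 200. The figure is chosen for the desk scale: the default
grid's effective voxels are about 4 mm, whose volume (and hence per-voxel
SNR) is roughly two orders of magnitude above the 1 mm isotropic clinical
regime, so a peak SNR of 200 is, if anything, conservative for the
structures being modeled.

What the generator does *not* emulate — and what passing tests therefore
do not demonstrate on real data: anatomical realism and partial-volume
texture, B0/B1 inhomogeneity beyond a smooth phase, susceptibility and
chemical shift (fat is just another T1/T2 class), motion and flow between
or within passes, eddy currents from the spoiler, and finite-duration RF
excitation of short-T2 species. The radial 64x64 experiments also carry an
irreducible error floor (about 11% NRMSE) from k-space corner truncation
of a piecewise-constant phantom; that floor belongs to the discrete test
object, not to the method, and it is why the exactness-style end-to-end
checks run at full Cartesian sampling while the undersampling behavior is
studied on the radial trajectory.

## Problem sizes

Default experiments run on 64x64 grids with 144 spokes x 64 samples
(somewhat above the 101-spoke radial Nyquist count for this grid), 6 (or,
in tests, 4) coils, and 8x4 reconstruction iterations; the 3D path is
exercised at 32^3. These sizes keep any single check in the seconds-to-
minutes range while leaving all operator contracts (adjointness, nesting,
closure identities) at full precision.

## Known limitations

* The L0 scheme offers no convergence or optimality guarantee; it is a
  fixed-budget heuristic, faithful to cited practice.
* Background-phase recovery is principal-branch only; amplitudes >= pi/2
  alias into the branch and rely on the extraction's sign invariance.
* k-space preconditioning is not implemented; the CG budget is small
  enough that it is unnecessary at these problem sizes.
* The 3D golden-means trajectory is one of several reasonable
  generalizations; any uniform center-out scheme with the nesting property
  would serve.
* Coil maps are synthetic or user-supplied; estimating them from data is
  out of scope.
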