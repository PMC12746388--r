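# psgre

Simulation and model-based reconstruction for **simultaneous bone-selective,
T1-weighted and T2-weighted MRI** from a single dual-pass, dual-echo,
partially RF-spoiled gradient-echo (PSGRE) acquisition.

Pediatric craniofacial imaging often needs both CT (for the skull) and MRI
(for soft tissue). A PSGRE steady state with a *small* quadratic RF phase
increment encodes tissue T2 in the **phase** of the complex steady-state
signal while the magnitude stays T1-weighted; adding an ultrashort second
echo per TR captures the rapidly decaying signal of cortical bone water
(T2 ≈ 0.3–0.4 ms). One scan then yields every soft-tissue contrast plus a
CT-like bone image — radiation-free. This package implements the full
model and pipeline on Bloch-simulated digital phantoms.

## The model

RF phase schedule (quadratic, increment θ):

    φ(n) = φ(n−1) + n·θ

* θ = 117° → ideal spoiling (pure T1w, Ernst magnitude);
* θ = 0° → coherent SSFP;
* θ = ±1.5° (default) → the signal phase becomes a monotone function of T2
  for T2 ≫ TR; flipping the sign of θ conjugates the signal.

Contrast extraction from the complex multi-contrast image x:

    x_ψ = | Re( x · e^{iψ} ) |          (π-periodic in ψ)

Two passes with opposite θ remove the background phase φ(r):

    x₊ x₋ = e^{2iφ(r)} |x|²  →  φ̂ = ½ arg(x₊x₋),
    x = ½ ( x₊ e^{−iφ̂} + (x₋ e^{−iφ̂})* )

Bone-selective image from the two echoes (UTE 80 µs, CTE 2.38 ms):

    x_s = (|x_UTE| − |x_CTE|) / (|x_UTE| + |x_CTE|) = tanh(ΔTE / 2T2)

computed directly or by early-terminated weighted least squares (quiet in
air). The four k-space datasets (2 echoes × 2 passes) are reconstructed
jointly with a joint-L0 wavelet penalty that forces one shared sparsity
support across all four images.

The package provides: isochromat and EPG steady-state simulators, seeded
head-like phantoms with coil maps and background phase, golden-angle
center-out ramp-up radial and Cartesian encoding (Kaiser-Bessel gridding
NUFFT, exact adjoints), CG and joint-L0 reconstruction, phase
estimation/pass combination/contrast extraction, bone imaging, NIfTI and
k-space-bundle I/O, an end-to-end pipeline driver and a CLI
(`inst/cli/psgre.R`).

## Worked example

```r
library(psgre)

sp <- seq_params()        # TR 5.5 ms, TE (80 us, 2.38 ms), flip 24, theta +1.5
wm  <- tissue_params(t1 = 850,  t2 = 70,   pd = 0.7, label = "wm")
csf <- tissue_params(t1 = 4000, t2 = 2000, pd = 1.0, label = "csf")
simulate_steady_state_epg(sp, wm)
#> steady-state signal: |s_ute| = 0.05862 (phase 0.6163 rad), |s_cte| = 0.05672; converged after 728 pulses
simulate_steady_state_epg(sp, csf)
#> steady-state signal: |s_ute| = 0.03468 (phase 1.411 rad), ...
```

CSF (long T2) has accumulated more than twice the phase of white matter —
that phase difference *is* the T2 encoding. The end-to-end pipeline
(phantom → encoding → joint reconstruction → phase correction →
extraction → bone image), here at full Cartesian sampling:

```r
res <- run_pipeline(pipeline_config(seed = 1, trajectory = "cartesian_full"))
round(res$metrics$nrmse, 4)
#> ute_pos ute_neg cte_pos cte_neg
#>  0.0018  0.0018  0.0017  0.0017
lapply(res$metrics$class_means, function(x) round(x, 4))
#> $psi_154                                  (T1-weighted extraction)
#>    air    fat   bone     wm     gm    csf
#> 0.0000 0.1391 0.0001 0.0560 0.0518 0.0200
#> $psi_066                                  (T2-weighted extraction)
#>    air    fat   bone     wm     gm    csf
#> 0.0000 0.0275 0.0000 0.0111 0.0197 0.0290
res$metrics$bone_mean_bone; res$metrics$bone_mean_soft
#> 0.957; 0.0166
```

Reading the numbers: the reconstructions match the simulated ground truth
to 0.2% NRMSE; at the auto-detected T1-weighted modulation (ψ = 154°) the
class means order WM > GM > CSF, at the T2-weighted one (ψ = 66°)
CSF > GM > WM — the two clinical orderings from a single dataset; and the
weighted-least-squares bone image averages 0.96 inside the bone shell
versus 0.017 in soft tissue (the tanh oracle gives 0.995 and ≤ 0.016).
The default radial configuration (`trajectory = "radial_golden"`, 144
spokes) exercises the clinical-style acquisition instead; at 64² it carries
an irreducible ~11% NRMSE floor from k-space corner truncation of the
discrete phantom (see the methods vignette).

The CLI mirrors the same stages:

```sh
Rscript inst/cli/psgre.R pipeline --seed 1 --out out/
Rscript inst/cli/psgre.R figures --out curves/
```

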