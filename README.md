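# xtalspec

Correction and kinetic analysis of UV–Vis absorption spectra recorded on
single macromolecular crystals.

## The problem

Absorption spectra measured through a protein crystal with a focused
fibre-optic microspectrophotometer are distorted by optical artefacts that
a solution measurement in a cuvette does not suffer: reflectivity at the
crystal/mother-liquor interfaces, diffuse Rayleigh scattering (rising
steeply toward the UV), a flat offset from focal-spot displacement,
detector saturation and low-flux lamp regions, and — in pump–probe
experiments — a spurious negative "dent" where the tail of the actinic
nanosecond laser pulse reaches the spectrometer. `xtalspec` models and
removes these artefacts and then analyses the corrected spectra: band time
traces with mono-exponential or Hill kinetic fits, and singular value
decomposition (SVD) of difference-spectrum series. It is aimed at
spectroscopists and crystallographers preparing or validating
time-resolved structural experiments.

## The models

**Absorbance** from the three recorded detector traces:

    A(λ) = −log10[ (I_sample(λ) − I_background(λ)) / (I_reference(λ) − I_background(λ)) ]

Points with non-positive net counts are masked, not clamped.

**Baseline.** The non-absorbing background is fitted on 1–3 user-chosen
baseline segments (weighted by per-segment divergence factors) and
subtracted:

    B(λ) = R(n₁(λ), n₂(λ)) + e/λ⁴ + const
    R(n₁, n₂) = ((n₁ − n₂)/(n₁ + n₂))²          (Fresnel, normal incidence)
    nᵢ(λ) = aᵢ + bᵢ/λ²                           (Cauchy dispersion)

with fitted parameters a, b, c, d (the two Cauchy media) and e (Rayleigh
amplitude). Fallbacks: pure Rayleigh `e/λ⁴ + const` and a custom power law
`e·λ⁻ⁿ + const` (useful for X-ray-induced baselines).

**Kinetics.** `y(t) = y∞ + (y₀ − y∞)·e^(−kt)` (decay/rise) and the Hill
form `y(t) = base + amp·tⁿ/(tⁿ + Kⁿ)`, fitted by Levenberg–Marquardt in
rescaled time.

**SVD.** Difference spectra are stacked chronologically into a matrix `A`
and decomposed into basis spectra (lSV), singular values, and time courses
(rSV), with a fixed sign convention (each basis spectrum's
largest-magnitude element is positive).

A synthetic-data module (`sim_spec()`, `simulate_traces()`,
`simulate_series()`, plus ready-made bacteriorhodopsin-photocycle and
LOV2-photoadduct scenarios) generates raw traces and kinetic series with
exactly these artefact structures, so the whole pipeline is testable
without instrument data.

## Worked example

A simulated bacteriorhodopsin photocycle series (12 spectra, 3 µs–1 s,
560 nm laser dent), dent removal, light − dark differences, and a Hill fit
to the 400 nm M-state band over 10–1000 µs:

```r
library(xtalspec)

sc  <- sim_scenario_br(seed = 1)
res <- remove_laser_dent(sc$series, fill = "mask")
res$masks[[1]]
#> <dent_mask> main dent 560.0 nm [552.0, 574.0], 0.457 OD; 0 minor dip(s)

d   <- difference_series(res$series, sc$dark)
tr  <- extract_time_trace(d, c(395, 405), "mean")
fit_kinetic(tr, "hill", fit_range = c(1e-5, 1e-3))
#> <kinetic_fit> model=hill, 5 points, RMS 0.0006959
#>   base = 0.000803435 +- 0.0017
#>   amplitude = 0.585505 +- 0.00283
#>   K = 9.90642e-05 +- 6.56e-07
#>   n = 2.03871 +- 0.033
```

The laser dent is found at its simulated position (560 nm), and the fitted
half-rise time `K` = 99.1 µs with Hill coefficient `n` = 2.04 recovers the
simulated M-state rise (100 µs, n = 2) to about 1%. The same chain runs
from a declarative YAML config through `run_pipeline()`, or from a shell
via the thin CLI at `inst/cli/xtalspec.R` (subcommands `simulate`, `abs`,
`smooth`, `baseline`, `run`).

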