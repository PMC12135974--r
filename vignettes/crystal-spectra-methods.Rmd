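---
title: "Correcting and analysing single-crystal absorption spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting and analysing single-crystal absorption spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xtalspec)
```

## Why crystal spectra need correction

A UV–Vis absorption spectrum measured through a single protein crystal
differs from the corresponding solution spectrum for purely optical
reasons. The focused beam crosses interfaces between air, mother liquor
and crystal, each reflecting a wavelength-dependent fraction of the light;
the dense crystal Rayleigh-scatters photons out of the collection cone
with the characteristic $\lambda^{-4}$ law; refraction displaces the focal
point and produces a flat apparent absorbance offset; and the detector
adds its own artefacts (saturation plateaus, low-flux lamp regions). In
pump–probe experiments the tail of the nanosecond actinic laser reaches
the spectrometer during integration and digs a spurious dip ("dent") into
the spectrum. `xtalspec` implements a correction and analysis workflow for
these data: absorbance computation from raw counts, baseline modelling and
subtraction, smoothing, dent removal, confidence scoring, band time traces
with kinetic fits, and SVD of difference-spectrum series.

## Absorbance and masking

With a dark trace $I_{background}$ (lamp off), a lamp reference
$I_{reference}$ (no sample), and the transmitted trace $I_{sample}$,

$$A(\lambda) = -\log_{10}
\frac{I_{sample}(\lambda)-I_{background}(\lambda)}
     {I_{reference}(\lambda)-I_{background}(\lambda)}.$$

Wherever either net count is non-positive there is no transmission
information; such points are **masked** rather than clamped or dropped, so
every downstream operation sees the full shared wavelength grid. Masks
propagate through differences, are skipped by band means, interpolated by
band integrals, and either interpolated or consistently dropped before
SVD.

## The baseline model

The default model composes the three physical contributions:

$$B(\lambda) = \left(\frac{n_1(\lambda)-n_2(\lambda)}
                         {n_1(\lambda)+n_2(\lambda)}\right)^2
             + \frac{e}{\lambda^4} + c_0,
\qquad n_i(\lambda) = a_i + \frac{b_i}{\lambda^2},$$

i.e. Fresnel reflectivity at normal incidence between two Cauchy-dispersive
media (one effective crystal/liquor interface), Rayleigh scattering, and a
constant absorbing the focal-spot loss. Five shape parameters ($a, b, c,
d, e$, in the field's conventional naming) plus the constant are fitted by
bounded Levenberg–Marquardt on the points of up to three user-chosen
non-absorbing segments — canonically a near-UV segment where scattering is
strongest, a peakless mid segment, and a red-side segment where it is
weakest. Reflectivity is fitted in OD units directly rather than as
$-\log_{10}(1-R)$: for $R \ll 1$ the two differ by a near-constant factor
that the data-driven parameters absorb.

Design notes:

* **Weights.** Each segment carries a positive *divergence* factor
  (default 1); every point is weighted $1/\text{divergence}$ of its owning
  segment. No per-length normalisation is applied — the user sets
  divergences inversely proportional to segment length if desired.
* **Offset.** When the spectrum does not return to baseline between the
  peak of interest and the UV, a fraction of the peak maximum can be
  subtracted from designated segments before fitting, forcing the fitted
  curve to run that far below those points.
* **Initialisation and bounds.** $a = 1.33$, $c = 1.45$ (water-like and
  protein-like indices), $b = d = 3000\ \mathrm{nm}^2$, $e$ from a
  one-parameter $\lambda^{-4}$ pre-fit, $c_0$ from the segment minimum;
  bounds $a, c \in [1, 2]$, $b, d \in [0, 10^5]$, $e \ge 0$. Up to five
  restarts jitter the shape starts by ±20% using a fixed factor table (no
  RNG), so fits are reproducible and independent of the session seed.
* **Identifiability.** The reflectivity term depends essentially on
  $(a - c)$ and $(b - d)$ against a nearly constant denominator, and is
  symmetric under swapping the two media, so the individual Cauchy
  coefficients are not identifiable from a single spectrum. The *curve*
  $B(\lambda)$ is; tests therefore assert curve recovery (within 1% of the
  peak amplitude on noiseless data) for the combined model, and
  parameter-level recovery for the identifiable variants
  (`rayleigh_only`, `power_law`).
* **Variants.** `rayleigh_only` ($e/\lambda^4 + c_0$) and fixed-$n$
  `power_law` are linear and solved exactly by weighted least squares;
  free $n$ is bounded to $[1, 8]$ and a bound hit is reported in the fit's
  notes. The power law is the pragmatic choice for X-ray-induced baseline
  changes, for which no first-principles form is available.
* **Segments are closed intervals**; boundary wavelengths belong to the
  segment.

The simpler constant-baseline correction subtracts the mean over a band
devoid of absorption and is idempotent. Peak scaling multiplies a spectrum
so that its maximum over a conserved band reaches a target (or 1); the
band maximum, rather than a single wavelength, is used for robustness to
single-pixel noise (a zero-width band recovers single-wavelength
behaviour).

## Smoothing

Savitzky–Golay smoothing (default: degree 3 over 21-point windows)
replaces each point by the centre value of the least-squares polynomial
over its window. Edge points reuse the full first/last window with the
polynomial evaluated at their own position — the classic `sgolayfilt` edge
treatment. We chose this over mirror padding because it preserves every
polynomial up to the filter degree *exactly*, including at the edges
(a mirrored cubic is no longer a cubic), which is also the property the
test suite asserts. Windows containing masked points are re-fitted on the
surviving points when at least `degree + 2` remain, otherwise the output
point is masked. A rolling mean with shrinking edge windows is available
as the simpler alternative. Both smoothers are linear operators; the
filter assumes an approximately uniform grid and warns when spacing varies
by more than 5%.

## Laser-dent detection and removal

Dips are located as local minima of the lightly smoothed spectrum whose
curvature at the bottom is positive. Boundaries come from the second
derivative (Savitzky–Golay differentiation, degree 3): walking outward
from the dip bottom, the flanking curvature shoulders are the local minima
of the second derivative, and the dip ends where the curvature returns to
zero. Two numerical choices matter:

* For an isolated Gaussian dip on a gently varying background the second
  derivative approaches zero *without* crossing it, so "zero" is taken
  with a relative tolerance (5% of the shoulder magnitude). The value also
  separates dent curvature from the much gentler curvature of a broad
  underlying absorption band; boundaries then land near $3.5\sigma$, where
  a 0.5 OD dent has decayed below 0.001 OD.
* A local maximum of the spectrum is a hard stop, so a dent on the flank
  of an absorption band can never eat past the band summit.

The dip amplitude is the depth from the straight line joining the
boundaries down to the minimum; dips below a prominence threshold (default
$5\times$ the robust noise level from the median absolute deviation of
first differences, floored at $10^{-3}$ OD) are ignored, and the
largest-amplitude dip is the laser dent (ties break toward shorter
wavelength). Across a kinetic series the dent is detected on the first
member; later members are searched only inside the first interval widened
by one smoothing window — the pump wavelength is fixed, so the dent can
only drift slightly — and members with no detectable dip have the template
interval removed. "Removal" masks the points (preserving the grid) or
bridges them by linear interpolation.

## Confidence scoring

The absorbance is unreliable wherever either lamp-lit trace has critically
low or saturated counts. Saturation is a run of at least `run_length`
(default 3) consecutive points within `tol` (default 0.5% of full scale)
of the detector ceiling. The per-trace score is a clipped linear ramp on
background-subtracted counts, zero at `low` (default 2% of full scale) and
one at `low + ramp` (default ramp 8%), zeroed on saturated runs; the
profile score is the pointwise minimum over sample and reference. The
functional form is a design choice — the requirement is only a monotone
score that flags both failure modes — and saturation of *either* trace
zeroes the score, the conservative reading. A criterion based on the
maximal meaningful variation of absorbance between neighbouring points is
deliberately out of scope.

## Kinetic fitting

Band time traces (mean or trapezoidal integral over a wavelength band) are
fitted with a mono-exponential
$y(t) = y_\infty + (y_0-y_\infty)e^{-kt}$ (rise and decay distinguished by
the sign of $y_0 - y_\infty$) or the Hill form
$y(t) = \mathrm{base} + \mathrm{amp}\,t^n/(t^n + K^n)$ with time as the
dose variable and free signs, so the same form fits rises and decays.
Initial guesses come from the trace (first/last values; the
half-amplitude crossing time for $1/k$ and $K$; $n = 1$). Fits run in
rescaled time $u = t/t_{1/2}$ so the rate parameter is of order one — on
log-spaced grids spanning six decades the raw-rate Jacobian column is
otherwise orders of magnitude smaller than the amplitude columns and
rank checks fail spuriously — and the optimiser is Levenberg–Marquardt
(`minpack.lm::nls.lm`) with positivity bounds on $k$, $K$, $n$. Parameter
uncertainties are $1\sigma$ from the converged fit's covariance. Constant
traces are rejected as degenerate before fitting. Log-spaced data are
fitted unweighted by default, with optional user weights. Amplitudes are
reported only relatively: crystal anisotropy and thickness make absolute
occupancies unreliable, which is also why serial-mode series (one
spectrum per crystal) are first rescaled so every member's conserved-band
maximum equals the series median.

## SVD of difference series

Difference spectra (light − dark, so static features cancel) are stacked
chronologically as rows of $A$ and thin-SVD'd. No mean-centering is
applied by default — differencing already removes the static signal. Signs
are fixed by flipping each basis spectrum so its largest-magnitude element
is positive (with the matching time course flipped too); explained
variance is $S_i^2/\sum_j S_j^2$; no automatic rank truncation is
performed — component selection stays with the user. Orthonormality and
full-rank reconstruction are asserted to $10^{-10}$ in the tests.
Component time courses feed back into the kinetic fitter; a linear model
is provided for drift components such as slow crystal displacement.

## The synthetic generator

`sim_spec()`/`simulate_traces()`/`simulate_series()` encode the forward
model the corrections assume: Gaussian absorption bands on a configurable
baseline, a smooth two-Gaussian lamp envelope scaled to 80% of a
16-bit-like full scale, a flat dark level (2% of full scale), saturation
clamping, fluorescence dips and laser dents as negative Gaussians, peak
amplitudes following exponential/Hill/linear laws (composable as
`amplitude * (base + coef * prod(terms))`, which expresses e.g. a
rise-then-decay intermediate or a partially depleted ground state), and
Gaussian noise applied last. Raw traces follow from the inverted
absorbance equation, so `compute_absorbance()` recovers the true
absorbance to $10^{-10}$ wherever no artefact applies — the identity every
fixture rests on. All generation is deterministic under the spec's seed,
via a local RNG scope that leaves the caller's stream untouched.

Two scenario presets define the study conditions used throughout the
tests:

* **Photocycle (BR-like).** A 600 nm ground band half-depleted while a
  400 nm intermediate band rises (Hill, half-rise 100 µs, $n = 2$) and
  decays (100 ms lifetime), on the standard 12-point logarithmic grid from
  3 µs to 1 s; a 560 nm dent (0.5 OD, $\sigma$ = 3 nm) decays by a factor
  0.55 per member; additive noise 0.002 OD.
* **Photoadduct relaxation (LOV2-like).** A difference shape with a
  negative 390 nm band and a dominant positive 420–500 nm band decaying
  mono-exponentially ($\tau$ = 300 s), plus a broad drift spectrum growing
  linearly in time, 16 points over one hour, noise $5\times10^{-4}$ OD.
  Three choices make this a clean two-process construction: the positive
  lobe dominates (as in the real photoadduct difference spectrum, and so
  the sign convention leaves the 390 nm band negative); the drift shape is
  orthogonalised against the kinetic shape, since SVD can only separate
  processes that are not collinear; and the collection extends to
  $\sim 12\tau$ — with shorter windows the drift's singular vector
  retains a deterministic exponential admixture (it is the Gram–Schmidt
  complement of the kinetic time course) that caps its linearity at
  $R^2 \approx 0.985$ no matter how small the noise. The drift stays a
  minor contaminant (~2% of the kinetic amplitude at its largest).

What the generator does **not** emulate: anisotropy/polarisation effects,
fluorescence self-absorption, wavelength-dependent detector response,
correlated (1/f) noise, and real lamp spectra. Passing tests therefore
demonstrate the correctness of the algorithms under the stated optical
model, not robustness to every instrumental pathology of real beamline
data.

## Pipeline and determinism

`run_pipeline()` chains the steps from one declarative YAML config
(simulate/read → absorbance → baseline → smooth → dedent → diff →
trace/fit/SVD). Step names and parameters are validated against a registry
before any file is touched. Every ASCII output carries the full history
header of the spectrum it holds; a JSON run log records steps, parameters
and MD5 checksums. Outputs contain no timestamps and all randomness flows
from the config seed, so re-running an identical config is byte-identical
— asserted in the tests. A thin command-line wrapper lives at
`inst/cli/xtalspec.R`.

## Problem sizes and limitations

Tests and the acceptance script use 501-point spectra (300–800 nm at
1 nm), 12–16-member series, and 100-replicate Monte-Carlo runs for the
kinetic recovery statistics; the full suite completes in a few seconds.
Known limitations: no polarisation/anisotropy correction (no algorithm
exists for the general case); fluorescence self-absorption cannot be
reliably modelled and is not attempted; only mono-exponential and Hill
kinetic models (no global multi-exponential analysis); no rotational
ambiguity resolution or target analysis on the SVD factors; baseline
Cauchy coefficients are reported but, as noted, only their combination is
physically meaningful.
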