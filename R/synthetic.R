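# Synthetic in crystallo spectra with the optical structure the corrections
# assume: Gaussian absorption bands on a reflectivity + Rayleigh baseline,
# detector noise, fluorescence dips, saturation plateaus, nanosecond-laser
# dents, and exponential / Hill time evolution. The forward model inverts
# the absorbance equation,
#   I_sample = I_bg + (I_ref - I_bg) * 10^(-A_true(lambda)),
# so that compute_absorbance() recovers A_true exactly wherever no
# artefact, noise or saturation applies.

# evaluate code with a local RNG state so generators are seed-deterministic
# without disturbing the caller's RNG
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  code
}

.gauss <- function(l, centre, sigma) exp(-((l - centre)^2) / (2 * sigma^2))

# one kinetic law evaluated on times t, as an occupancy-like factor
.law_factor <- function(law, t) {
  switch(law$type,
    exp_decay = exp(-law$k * t),
    exp_rise = 1 - exp(-law$k * t),
    hill = ifelse(t <= 0, 0, t^law$n / (t^law$n + law$K^law$n)),
    linear = law$slope * t,
    stop("unknown kinetic law: ", law$type))
}

# peak amplitude over time: amplitude * (base + coef * prod(terms))
.peak_amplitude <- function(peak, t) {
  if (is.null(peak$law)) return(rep(peak$amplitude, length(t)))
  law <- peak$law
  f <- rep(1, length(t))
  for (term in law$terms) f <- f * .law_factor(term, t)
  amp <- peak$amplitude * (law$base + law$coef * f)
  if (any(amp < -1e-12)) stop("kinetic law drove a peak amplitude negative")
  pmax(amp, 0)
}

#' Specification of a synthetic in crystallo spectrum
#'
#' Collects everything the generator needs: absorption peaks (with optional
#' kinetic laws), a baseline model, noise levels, optical artefacts, a time
#' grid, and the RNG seed. Defaults describe a clean single-peak crystal
#' spectrum on a Fresnel + Rayleigh baseline over 300-800 nm.
#'
#' @param grid Wavelength grid (nm, strictly increasing).
#' @param peaks List of peaks: `list(centre =, sigma =, amplitude =, law =)`
#'   with amplitude in OD; `law` is `NULL` (constant) or
#'   `list(base =, coef =, terms = list(...))` where each term is one of
#'   `list(type = "exp_decay", k =)`, `list(type = "exp_rise", k =)`,
#'   `list(type = "hill", K =, n =)`, `list(type = "linear", slope =)`;
#'   the amplitude at time t is `amplitude * (base + coef * prod(terms))`.
#' @param baseline `list(variant =, params =)` as in
#'   [fit_scattering_baseline()], or `NULL` for none.
#' @param noise `list(multiplicative =, additive =, od_sigma =)`: fractional
#'   Gaussian noise and additive count noise on raw traces, and additive OD
#'   noise on simulated absorbance series.
#' @param artefacts Optional list: `fluorescence_dip = list(centre, sigma,
#'   depth)` (OD), `laser_dent = list(centre, sigma, depth, member_decay)`
#'   (depth decays by `member_decay` per successive series member),
#'   `saturation = list(band, factor)` (lamp boost driving the reference
#'   into the detector ceiling).
#' @param times Time grid (s) for series generation.
#' @param full_scale Detector full-scale counts.
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @return A `sim_spec` object.
#' @export
sim_spec <- function(grid = seq(300, 800, by = 1),
                     peaks = list(list(centre = 430, sigma = 15, amplitude = 0.8,
                                       law = NULL)),
                     baseline = list(variant = "fresnel_rayleigh",
                                     params = list(a = 1.33, b = 3000, c = 1.50,
                                                   d = 4200, e = 2e9, const = 0)),
                     noise = list(multiplicative = 0, additive = 0, od_sigma = 0),
                     artefacts = list(),
                     times = NULL,
                     full_scale = 65535,
                     seed = 1) {
  stopifnot(all(diff(grid) > 0))
  for (p in peaks) {
    if (p$amplitude < 0) stop("peak amplitudes must be >= 0")
    if (p$sigma <= 0) stop("peak sigma must be > 0")
  }
  structure(list(grid = grid, peaks = peaks, baseline = baseline,
                 noise = noise, artefacts = artefacts, times = times,
                 full_scale = full_scale, seed = as.integer(seed)),
            class = "sim_spec")
}

# true absorbance at one time point (t = NULL: static amplitudes)
.a_true <- function(spec, t = NULL, member_index = 1L) {
  l <- spec$grid
  a <- rep(0, length(l))
  for (p in spec$peaks) {
    amp <- if (is.null(t)) p$amplitude else .peak_amplitude(p, t)
    a <- a + amp * .gauss(l, p$centre, p$sigma)
  }
  if (!is.null(spec$baseline))
    a <- a + .baseline_eval(spec$baseline$variant, spec$baseline$params)(l)
  fd <- spec$artefacts$fluorescence_dip
  if (!is.null(fd)) a <- a - fd$depth * .gauss(l, fd$centre, fd$sigma)
  ld <- spec$artefacts$laser_dent
  if (!is.null(ld)) {
    decay <- if (is.null(ld$member_decay)) 1 else ld$member_decay
    a <- a - ld$depth * decay^(member_index - 1L) * .gauss(l, ld$centre, ld$sigma)
  }
  a
}

#' Simulate raw sample/reference/background traces
#'
#' The lamp reference is a smooth two-Gaussian envelope scaled to 80% of
#' the detector full scale; the background is a flat dark level; the sample
#' trace follows from the true absorbance through the inverted absorbance
#' equation. A saturation artefact boosts the lamp inside a band so both
#' lamp-lit traces clamp at the detector ceiling there. Noise is applied
#' last; output is deterministic under the spec's seed.
#'
#' @param spec A [sim_spec()].
#' @return List with `sample`, `reference`, `background` ([raw_trace()]s)
#'   and `truth` (the noise-free true-absorbance [spectrum()]).
#' @export
simulate_traces <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  l <- spec$grid
  fs <- spec$full_scale
  envelope <- .gauss(l, 480, 120) + 0.6 * .gauss(l, 650, 150)
  ref <- envelope / max(envelope) * 0.8 * fs
  sat <- spec$artefacts$saturation
  if (!is.null(sat)) {
    idx <- band_indices(l, sat$band)
    ref[idx] <- ref[idx] * sat$factor
  }
  bg <- rep(0.02 * fs, length(l))
  a_true <- .a_true(spec, t = NULL)
  smp <- bg + (ref - bg) * 10^(-a_true)
  with_seed(spec$seed, {
    noisy <- function(x) {
      if (spec$noise$multiplicative > 0)
        x <- x * (1 + stats::rnorm(length(x), 0, spec$noise$multiplicative))
      if (spec$noise$additive > 0)
        x <- x + stats::rnorm(length(x), 0, spec$noise$additive)
      x
    }
    smp <- noisy(smp); ref <- noisy(ref); bg_n <- noisy(bg)
    clamp <- function(x) pmin(pmax(x, 0), fs)
    list(sample = raw_trace(l, clamp(smp), "sample", detector_full_scale = fs,
                            source_id = "simulated"),
         reference = raw_trace(l, clamp(ref), "reference", detector_full_scale = fs,
                               source_id = "simulated"),
         background = raw_trace(l, clamp(bg_n), "background", detector_full_scale = fs,
                                source_id = "simulated"),
         truth = spectrum(l, a_true, kind = "absorbance", label = "truth"))
  })
}

#' Simulate a kinetic series of absorbance spectra
#'
#' One absorbance spectrum per time point, with peak amplitudes following
#' their kinetic laws, the optional laser dent decaying across members, an
#' optional additive drift spectrum growing linearly with time, and
#' additive OD noise. Deterministic under the spec's seed.
#'
#' @param spec A [sim_spec()] with a non-empty `times`.
#' @param drift Optional `list(shape =, slope =)`: `shape` is a numeric
#'   vector on the grid (or `list(centre, sigma, amplitude)` for a
#'   Gaussian), added as `slope * t * shape`.
#' @return A time-axis [spectrum_series()]; the noise-free member spectra
#'   are attached as the `"truth"` attribute.
#' @export
simulate_series <- function(spec, drift = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  if (is.null(spec$times) || !length(spec$times)) stop("spec$times must be non-empty")
  l <- spec$grid
  dshape <- NULL
  if (!is.null(drift)) {
    dshape <- if (is.list(drift$shape))
      drift$shape$amplitude * .gauss(l, drift$shape$centre, drift$shape$sigma)
    else drift$shape
  }
  truth <- lapply(seq_along(spec$times), function(i) {
    a <- .a_true(spec, t = spec$times[i], member_index = i)
    if (!is.null(dshape)) a <- a + drift$slope * spec$times[i] * dshape
    a
  })
  members <- with_seed(spec$seed, lapply(seq_along(spec$times), function(i) {
    a <- truth[[i]]
    if (spec$noise$od_sigma > 0)
      a <- a + stats::rnorm(length(a), 0, spec$noise$od_sigma)
    spectrum(l, a, kind = "absorbance", label = spec$times[i])
  }))
  out <- spectrum_series(members, axis = "time", labels = spec$times)
  attr(out, "truth") <- truth
  out
}

#' Bacteriorhodopsin-like photocycle scenario
#'
#' A ground-state band at 600 nm that is half depleted while the M-state
#' band at 400 nm rises (Hill-like, half-rise at 100 microseconds) and then
#' decays back (100 ms lifetime), on the standard 12-point logarithmic time
#' grid from 3 microseconds to 1 second, with a 560 nm nanosecond-laser
#' dent decaying across members. The dark (ground-state) spectrum is
#' returned alongside for difference-spectrum construction.
#'
#' @param seed Integer seed.
#' @param od_sigma Additive OD noise per point (default 0.002).
#' @param dent Include the laser dent (default `TRUE`).
#' @return List: `series`, `dark` (ground-state spectrum), `spec` (the
#'   [sim_spec()] used), `m_law` (the shared M-state occupancy terms).
#' @export
sim_scenario_br <- function(seed = 1, od_sigma = 0.002, dent = TRUE) {
  times <- c(3e-6, 1e-5, 3e-5, 1e-4, 3e-4, 1e-3, 3e-3, 1e-2, 3e-2, 1e-1, 3e-1, 1)
  m_terms <- list(list(type = "hill", K = 1e-4, n = 2),
                  list(type = "exp_decay", k = 10))
  peaks <- list(
    list(centre = 600, sigma = 40, amplitude = 1.0,
         law = list(base = 1, coef = -0.5, terms = m_terms)),
    list(centre = 400, sigma = 20, amplitude = 0.6,
         law = list(base = 0, coef = 1, terms = m_terms)))
  artefacts <- if (dent)
    list(laser_dent = list(centre = 560, sigma = 3, depth = 0.5, member_decay = 0.55))
  else list()
  spec <- sim_spec(grid = seq(300, 800, by = 1), peaks = peaks,
                   baseline = list(variant = "rayleigh_only",
                                   params = list(e = 5e8, const = 0.05)),
                   noise = list(multiplicative = 0, additive = 0, od_sigma = od_sigma),
                   artefacts = artefacts, times = times, seed = seed)
  dark_spec <- sim_spec(grid = spec$grid,
                        peaks = list(list(centre = 600, sigma = 40, amplitude = 1.0,
                                          law = NULL)),
                        baseline = spec$baseline, times = NULL, seed = seed)
  dark <- spectrum(spec$grid, .a_true(dark_spec), kind = "absorbance", label = 0)
  list(series = simulate_series(spec), dark = dark, spec = spec, m_law = m_terms)
}

#' LOV2-like photoadduct relaxation scenario
#'
#' A two-process series built for SVD: a difference shape with a negative
#' photoadduct band at 390 nm and a dominant positive ground-state band
#' spanning 420-500 nm, whose amplitude decays mono-exponentially (5 min
#' lifetime), plus a broad drift spectrum growing linearly with time
#' (crystal displacement during collection), on a 16-point linear time grid
#' over one hour -- the collection extends well past relaxation completion,
#' as in practice. The drift shape is orthogonalized against the kinetic
#' difference shape so the two processes are spectrally separable, and it
#' stays a minor contaminant (a few percent of the kinetic amplitude), as
#' expected for a crystal slowly slipping in its loop.
#'
#' @param seed Integer seed.
#' @param k Relaxation rate constant (1/s), default `1/300`.
#' @param drift_slope Drift growth per second (OD/s at the raw drift-shape
#'   maximum), default `2e-6`.
#' @param od_sigma Additive OD noise (default 5e-4).
#' @return List: `series`, `dark`, `k`, `spec`.
#' @export
sim_scenario_lov2 <- function(seed = 1, k = 1 / 300, drift_slope = 2e-6,
                              od_sigma = 5e-4) {
  grid <- seq(320, 560, by = 1)
  times <- seq(0, 3600, length.out = 16)
  base_vals <- 0.8 * .gauss(grid, 450, 40) + 0.4 * .gauss(grid, 390, 15) + 0.1
  shape <- -0.25 * .gauss(grid, 390, 12) + 0.4 * .gauss(grid, 460, 45)
  drift_shape <- .gauss(grid, 430, 60)
  drift_shape <- drift_shape - sum(drift_shape * shape) / sum(shape^2) * shape
  truth <- lapply(times, function(t)
    base_vals + shape * exp(-k * t) + drift_slope * t * drift_shape)
  members <- with_seed(seed, lapply(seq_along(times), function(i) {
    a <- truth[[i]]
    if (od_sigma > 0) a <- a + stats::rnorm(length(a), 0, od_sigma)
    spectrum(grid, a, kind = "absorbance", label = times[i])
  }))
  series <- spectrum_series(members, axis = "time", labels = times)
  attr(series, "truth") <- truth
  dark <- spectrum(grid, base_vals, kind = "absorbance", label = "dark")
  list(series = series, dark = dark, k = k, drift_slope = drift_slope,
       shape = shape, drift_shape = drift_shape,
       spec = list(grid = grid, times = times, seed = seed))
}
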