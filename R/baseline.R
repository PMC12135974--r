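# Baseline modelling for in crystallo absorption spectra.
#
# The apparent background of a single-crystal absorption spectrum combines
# achromatic reflectivity at the crystal/liquor interface (Fresnel, with
# wavelength-dependent refractive indices given by Cauchy dispersion),
# diffuse Rayleigh scattering (lambda^-4), and a flat offset from focal-spot
# displacement. The combined model fitted here is
#
#   B(lambda) = ((n1 - n2)/(n1 + n2))^2 + e / lambda^4 + const
#   n1 = a + b / lambda^2,   n2 = c + d / lambda^2
#
# with one effective interface; a, b, c, d, e are fitted to points drawn
# from up to three user-chosen non-absorbing segments. Fallback variants:
# pure Rayleigh (e/lambda^4 + const) and a custom power law
# (e * lambda^-n + const), useful for X-ray-induced baseline changes.

#' Fresnel reflectivity at normal incidence
#'
#' Fraction of light reflected at an interface between media of refractive
#' indices `n1` and `n2`: `((n1 - n2)/(n1 + n2))^2`.
#'
#' @param n1,n2 Refractive indices (> 0); vectors recycle.
#' @return Reflectivity in \[0, 1).
#' @export
fresnel_reflectivity <- function(n1, n2) {
  if (any(n1 <= 0) || any(n2 <= 0)) stop("refractive indices must be > 0")
  ((n1 - n2) / (n1 + n2))^2
}

#' Cauchy dispersion relation
#'
#' Empirical refractive index of a transparent medium,
#' `n(lambda) = a + b / lambda^2` with `b` in nm^2.
#'
#' @param a,b Cauchy coefficients.
#' @param lambda Wavelength in nm (> 0).
#' @return Refractive index.
#' @export
cauchy_index <- function(a, b, lambda) {
  if (any(lambda <= 0)) stop("wavelength must be > 0")
  a + b / lambda^2
}

#' Baseline-segment configuration
#'
#' Defines the 1-3 non-absorbing wavelength segments whose points constrain
#' the baseline fit (canonically: a near-UV segment where scattering is
#' strongest, a peakless mid segment, and a red-side segment where it is
#' weakest), a positive divergence factor per segment that down-weights it
#' (per-point weight is `1/divergence`; larger = less influence), and an
#' optional constant offset between the fit and the data, expressed as a
#' fraction of the maximum absorbance of the peak of interest and applied
#' to designated segments.
#'
#' @param segments List of `c(lo, hi)` wavelength intervals (nm), closed,
#'   non-overlapping.
#' @param divergence Positive factor per segment (default 1).
#' @param offset_fraction Fraction of the peak maximum, >= 0 (default 0).
#' @param offset_segment Integer indices of segments the offset applies to
#'   (default: all, when `offset_fraction > 0`).
#' @return A `segment_config` object.
#' @export
segment_config <- function(segments, divergence = NULL, offset_fraction = 0,
                           offset_segment = NULL) {
  if (!is.list(segments)) segments <- list(segments)
  if (length(segments) < 1 || length(segments) > 3)
    stop("1 to 3 segments required")
  for (sg in segments)
    if (length(sg) != 2 || sg[2] <= sg[1]) stop("each segment must be c(lo, hi), hi > lo")
  ord <- order(vapply(segments, `[`, numeric(1), 1))
  so <- segments[ord]
  for (i in seq_len(length(so) - 1))
    if (so[[i + 1]][1] <= so[[i]][2]) stop("segments must not overlap")
  if (is.null(divergence)) divergence <- rep(1, length(segments))
  if (length(divergence) != length(segments) || any(divergence <= 0))
    stop("one positive divergence factor per segment required")
  if (offset_fraction < 0) stop("offset_fraction must be >= 0")
  if (is.null(offset_segment))
    offset_segment <- if (offset_fraction > 0) seq_along(segments) else integer(0)
  structure(list(segments = segments, divergence = divergence,
                 offset_fraction = offset_fraction,
                 offset_segment = offset_segment),
            class = "segment_config")
}

#' Constant-baseline correction
#'
#' Subtracts the mean absorbance over a band devoid of absorption, bringing
#' spectra onto a common zero baseline. Masked points are ignored when
#' computing the mean. Idempotent.
#'
#' @param s A [spectrum()].
#' @param band `c(lo, hi)` nm, intersecting the grid in >= 3 points.
#' @return Corrected spectrum; the band and subtracted mean are recorded in
#'   the history.
#' @export
constant_baseline_correct <- function(s, band) {
  idx <- band_indices(s$wavelengths, band)
  if (length(idx) < 3) stop("band must contain at least 3 grid points")
  idx <- idx[!s$mask[idx]]
  if (length(idx) == 0) stop("all points in the reference band are masked")
  m <- mean(s$values[idx])
  s$values <- s$values - m
  add_history(s, "constant_baseline_correct",
              list(band = band, subtracted = m))
}

# model functions per variant ------------------------------------------------

.baseline_eval <- function(variant, params) {
  force(params)
  switch(variant,
    fresnel_rayleigh = function(l) {
      n1 <- params[["a"]] + params[["b"]] / l^2
      n2 <- params[["c"]] + params[["d"]] / l^2
      ((n1 - n2) / (n1 + n2))^2 + params[["e"]] / l^4 + params[["const"]]
    },
    rayleigh_only = function(l) params[["e"]] / l^4 + params[["const"]],
    power_law = function(l) params[["e"]] * l^(-params[["n"]]) + params[["const"]],
    stop("unknown variant: ", variant))
}

# deterministic multi-start jitter factors (+-20%), no RNG involved
.jitter_table <- rbind(
  c(1.0, 1.0, 1.0, 1.0),
  c(0.8, 1.2, 1.0, 1.0),
  c(1.2, 0.8, 1.0, 1.0),
  c(1.0, 1.0, 0.8, 1.2),
  c(1.1, 0.9, 1.2, 0.8)
)

#' Fit a scattering + reflectivity baseline model
#'
#' Weighted nonlinear least squares of the chosen baseline variant against
#' the points of the configured non-absorbing segments (per-point weight
#' `1/divergence` of the owning segment). When an offset fraction is set,
#' `offset_fraction * max(values in max_peak_band)` is subtracted from the
#' observed values of the designated segments before fitting, so the fitted
#' baseline runs below those points by that constant.
#'
#' Variants: `"fresnel_rayleigh"` (Fresnel reflectivity between two Cauchy
#' media plus Rayleigh `e/lambda^4` plus a constant; parameters `a`-`e`),
#' `"rayleigh_only"` (`e/lambda^4 + const`, solved as a weighted linear
#' fit), `"power_law"` (`e * lambda^-n + const`; `n` fixed by the user or
#' fitted within \[1, 8\]).
#'
#' @param s A [spectrum()].
#' @param cfg A [segment_config()].
#' @param variant Model variant, see above.
#' @param max_peak_band `c(lo, hi)` band holding the peak of interest; only
#'   needed when `cfg$offset_fraction > 0`.
#' @param n Power-law exponent; `NULL` (fit within \[1, 8\]) or a fixed
#'   value.
#' @return A `baseline_fit` object: `variant`, named `params` (including
#'   `const`), per-segment RMS residuals, an `evaluate(lambda)` closure, and
#'   a `diagnostic` data frame (full grid, observed, fitted, segment
#'   membership) for plotting or ASCII export.
#' @export
fit_scattering_baseline <- function(s, cfg,
                                    variant = c("fresnel_rayleigh", "rayleigh_only", "power_law"),
                                    max_peak_band = NULL, n = NULL) {
  variant <- match.arg(variant)
  stopifnot(inherits(s, "spectrum"), inherits(cfg, "segment_config"))
  seg_of <- rep(NA_integer_, length(s$wavelengths))
  for (i in seq_along(cfg$segments)) {
    idx <- band_indices(s$wavelengths, cfg$segments[[i]])
    seg_of[idx] <- i
  }
  use <- !is.na(seg_of) & !s$mask
  if (sum(use) < 5) stop("segments must contain at least 5 unmasked points")
  for (i in seq_along(cfg$segments))
    if (length(unique(s$wavelengths[use & seg_of == i])) < 2)
      stop("degenerate segment ", i, ": fewer than 2 distinct wavelengths")
  l <- s$wavelengths[use]
  y <- s$values[use]
  seg <- seg_of[use]
  w <- 1 / cfg$divergence[seg]
  offset <- 0
  if (cfg$offset_fraction > 0) {
    if (is.null(max_peak_band))
      stop("max_peak_band required when offset_fraction > 0")
    pk <- band_indices(s$wavelengths, max_peak_band)
    pk <- pk[!s$mask[pk]]
    if (!length(pk)) stop("max_peak_band contains no unmasked points")
    offset <- cfg$offset_fraction * max(s$values[pk])
    y[seg %in% cfg$offset_segment] <- y[seg %in% cfg$offset_segment] - offset
  }

  # one-parameter lambda^-4 pre-fit used for initialisation
  prefit_e <- function() {
    x <- 1 / l^4
    max(0, sum(w * x * (y - min(y))) / sum(w * x^2))
  }

  notes <- character(0)
  if (variant == "rayleigh_only") {
    fit <- stats::lm(y ~ I(1 / l^4), weights = w)
    params <- c(e = unname(stats::coef(fit)[2]), const = unname(stats::coef(fit)[1]))
  } else if (variant == "power_law" && !is.null(n)) {
    fit <- stats::lm(y ~ I(l^(-n)), weights = w)
    params <- c(e = unname(stats::coef(fit)[2]), const = unname(stats::coef(fit)[1]),
                n = n)
  } else if (variant == "power_law") {
    df <- data.frame(l = l, y = y)
    start0 <- list(e = max(prefit_e(), 1e-6), n = 4, const = min(y))
    fit <- .nls_multistart(y ~ e * l^(-n) + const, df, w, start0,
                           lower = c(e = 0, n = 1, const = -Inf),
                           upper = c(e = Inf, n = 8, const = Inf))
    params <- stats::coef(fit)
    if (params[["n"]] <= 1 + 1e-6 || params[["n"]] >= 8 - 1e-6)
      notes <- c(notes, sprintf("power-law exponent n = %.3f hit a bound of [1, 8]", params[["n"]]))
  } else {
    df <- data.frame(l = l, y = y)
    start0 <- list(a = 1.33, b = 3000, c = 1.45, d = 3000,
                   e = prefit_e(), const = min(y))
    fit <- .nls_multistart(
      y ~ ((a + b / l^2 - c - d / l^2) / (a + b / l^2 + c + d / l^2))^2 +
        e / l^4 + const,
      df, w, start0,
      lower = c(a = 1, b = 0, c = 1, d = 0, e = 0, const = -Inf),
      upper = c(a = 2, b = 1e5, c = 2, d = 1e5, e = Inf, const = Inf))
    params <- stats::coef(fit)
  }
  params <- as.list(params)
  evaluate <- .baseline_eval(variant, params)
  res <- y - evaluate(l)
  seg_rms <- vapply(seq_along(cfg$segments),
                    function(i) sqrt(mean(res[seg == i]^2)), numeric(1))
  diagnostic <- data.frame(wavelength = s$wavelengths,
                           observed = ifelse(s$mask, NA_real_, s$values),
                           fitted = evaluate(s$wavelengths),
                           segment = ifelse(is.na(seg_of), 0L, seg_of))
  structure(list(variant = variant, params = params, offset = offset,
                 segment_rms = seg_rms, evaluate = evaluate,
                 diagnostic = diagnostic, config = cfg, notes = notes),
            class = "baseline_fit")
}

# bounded Levenberg-Marquardt with deterministic multi-start restarts
.nls_multistart <- function(formula, data, weights, start0, lower, upper) {
  environment(formula) <- environment()  # so nlsLM resolves `weights` here
  pn <- names(start0)
  best <- NULL
  best_rss <- Inf
  errs <- character(0)
  for (j in seq_len(nrow(.jitter_table))) {
    fac <- .jitter_table[j, ]
    start <- start0
    # jitter the shape parameters only (first up to 4), keep const
    for (k in seq_len(min(4, length(pn)))) {
      nm <- pn[k]
      if (nm != "const") {
        v <- start0[[nm]] * fac[k]
        start[[nm]] <- min(max(v, lower[[nm]]), if (is.finite(upper[[nm]])) upper[[nm]] else v)
      }
    }
    fit <- tryCatch(
      minpack.lm::nlsLM(formula, data = data, start = start, weights = weights,
                        lower = lower[pn], upper = upper[pn],
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) e)
    if (inherits(fit, "error")) { errs <- c(errs, conditionMessage(fit)); next }
    rss <- sum(stats::residuals(fit)^2 * weights)
    if (rss < best_rss) { best <- fit; best_rss <- rss }
  }
  if (is.null(best))
    stop("baseline fit did not converge after restarts: ",
         paste(unique(errs), collapse = "; "))
  best
}

#' @export
print.baseline_fit <- function(x, ...) {
  cat(sprintf("<baseline_fit> variant=%s\n  params: %s\n  segment RMS: %s\n",
              x$variant,
              paste(names(x$params), sprintf("%.6g", unlist(x$params)),
                    sep = "=", collapse = ", "),
              paste(sprintf("%.3g", x$segment_rms), collapse = ", ")))
  for (nt in x$notes) cat("  note:", nt, "\n")
  invisible(x)
}

#' Subtract a fitted baseline from a spectrum
#'
#' Evaluates the fitted baseline model on the spectrum's grid and subtracts
#' it, bringing the baseline to zero. Masked points stay masked.
#'
#' @param s A [spectrum()].
#' @param fit A `baseline_fit` from [fit_scattering_baseline()].
#' @return Corrected spectrum.
#' @export
subtract_baseline <- function(s, fit) {
  stopifnot(inherits(fit, "baseline_fit"))
  s$values <- s$values - fit$evaluate(s$wavelengths)
  add_history(s, "subtract_baseline",
              list(variant = fit$variant, params = fit$params))
}

#' Export the baseline diagnostic as ASCII
#'
#' Writes grid, observed, fitted-baseline and segment-membership columns so
#' the quality of the segment choice can be assessed in any plotting tool.
#'
#' @param fit A `baseline_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_baseline_diagnostic <- function(fit, path) {
  d <- fit$diagnostic
  lines <- c("# xtalspec baseline diagnostic",
             paste0("# variant: ", fit$variant),
             paste0("# params: ", paste(names(fit$params),
                                        sprintf("%.12g", unlist(fit$params)),
                                        sep = "=", collapse = ", ")),
             "# columns: wavelength observed fitted segment",
             sprintf("%.12g %s %.12g %d", d$wavelength,
                     ifelse(is.na(d$observed), "nan", sprintf("%.12g", d$observed)),
                     d$fitted, d$segment))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
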