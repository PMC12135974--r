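# Band time traces and kinetic model fitting.
#
# A time trace tracks the absorbance of a spectral band (mean, or
# trapezoidal band integral for serial one-spectrum-per-crystal data)
# across a kinetic series. Mono-exponential and Hill models are fitted by
# Levenberg-Marquardt least squares:
#
#   exponential:  y(t) = y_inf + (y0 - y_inf) * exp(-k t)      (k > 0)
#   Hill:         y(t) = base + amplitude * t^n / (t^n + K^n)  (K, n > 0)
#
# Rise and decay are the same exponential form, distinguished by the sign
# of (y0 - y_inf); base/amplitude signs are free in the Hill form so it
# fits rises and decays alike. The fitted rate constant estimates an
# intermediate-state lifetime for planning time-resolved experiments.

#' Extract a band time trace from a spectral series
#'
#' @param series A [spectrum_series()].
#' @param band `c(lo, hi)` nm intersecting the grid.
#' @param mode `"mean"` (band-average OD; masked points skipped) or
#'   `"integral"` (trapezoidal band integral, OD nm; masked points linearly
#'   interpolated first so the integration grid is complete).
#' @return A `time_trace`: `times` (series labels), `values`, `band`,
#'   `mode`.
#' @export
extract_time_trace <- function(series, band, mode = c("mean", "integral")) {
  mode <- match.arg(mode)
  stopifnot(inherits(series, "spectrum_series"))
  grid <- series$members[[1]]$wavelengths
  idx <- band_indices(grid, band)
  if (!length(idx)) stop("band does not intersect the wavelength grid")
  values <- vapply(seq_along(series$members), function(i) {
    m <- series$members[[i]]
    if (all(m$mask[idx]))
      stop("band fully masked in member ", i, " (label ", format(m$label), ")")
    if (mode == "mean") {
      mean(m$values[idx][!m$mask[idx]])
    } else {
      v <- m$values
      if (any(m$mask)) {
        ok <- !m$mask
        v <- stats::approx(grid[ok], v[ok], xout = grid, rule = 2)$y
      }
      if (length(idx) < 2) return(v[idx] * 0)
      sum(diff(grid[idx]) * (v[idx][-1] + v[idx][-length(idx)]) / 2)
    }
  }, numeric(1))
  structure(list(times = series$labels, values = values, band = band,
                 mode = mode, axis = series$axis),
            class = "time_trace")
}

#' @export
print.time_trace <- function(x, ...) {
  cat(sprintf("<time_trace> %d points, band [%.1f, %.1f] nm, mode=%s\n",
              length(x$times), x$band[1], x$band[2], x$mode))
  invisible(x)
}

.kin_model <- function(model, p) {
  switch(model,
    exp_decay = ,
    exp_rise = function(t) p[["y_inf"]] + (p[["y0"]] - p[["y_inf"]]) * exp(-p[["k"]] * t),
    hill = function(t) p[["base"]] + p[["amplitude"]] * t^p[["n"]] / (t^p[["n"]] + p[["K"]]^p[["n"]]),
    linear = function(t) p[["intercept"]] + p[["slope"]] * t)
}

#' Fit a kinetic model to a time trace
#'
#' Nonlinear least squares (Levenberg-Marquardt) of a mono-exponential
#' decay/rise, the Hill equation (with time as the dose variable), or a
#' straight line (for drift components). Initial guesses are derived from
#' the trace: first/last values for the plateaus, the half-amplitude
#' crossing time for `1/k` and `K`, and `n = 1` for the Hill coefficient.
#' Parameter uncertainties (1 sigma) come from the covariance of the
#' converged fit.
#'
#' @param trace A `time_trace`, or anything with numeric `times` and
#'   `values`.
#' @param model `"exp_decay"`, `"exp_rise"`, `"hill"`, or `"linear"`.
#' @param fit_range Optional `c(t0, t1)` restricting the points used.
#' @param weights Optional per-point weights.
#' @return A `kinetic_fit`: `model`, `params`, `stderr`, `fit_range`,
#'   `rms`, and `predict(t)`.
#' @export
fit_kinetic <- function(trace, model = c("exp_decay", "exp_rise", "hill", "linear"),
                        fit_range = NULL, weights = NULL) {
  model <- match.arg(model)
  t_all <- as.numeric(trace$times)
  y_all <- as.numeric(trace$values)
  keep <- is.finite(t_all) & is.finite(y_all)
  if (!is.null(fit_range))
    keep <- keep & t_all >= fit_range[1] & t_all <= fit_range[2]
  t <- t_all[keep]; y <- y_all[keep]
  if (is.null(weights)) w <- rep(1, length(t)) else w <- weights[keep]
  npar <- switch(model, linear = 2L, hill = 4L, 3L)
  need <- switch(model, hill = 5L, linear = 2L, 4L)
  if (length(t) < max(npar, need))
    stop("too few points in fit_range for a ", model, " fit (need ", need, ")")

  if (model == "linear") {
    fit <- stats::lm(y ~ t, weights = w)
    co <- stats::coef(fit)
    params <- list(intercept = unname(co[1]), slope = unname(co[2]))
    se <- sqrt(diag(stats::vcov(fit)))
    stderr <- list(intercept = unname(se[1]), slope = unname(se[2]))
    r2 <- summary(fit)$r.squared
  } else {
    if (model == "hill" && any(t <= 0))
      stop("Hill fits require strictly positive times")
    if (diff(range(y)) <= 1e-10 * max(abs(y), 1))
      stop("degenerate input: the trace is constant, no rate can be fitted ",
           "(range ", sprintf("%.3g", diff(range(y))), ")")
    # half-amplitude crossing for the rate scale
    y0g <- y[1]; yIg <- y[length(y)]
    half <- (y0g + yIg) / 2
    cross <- which(diff(sign(y - half)) != 0)
    t_half <- if (length(cross)) {
      i <- cross[1]
      t[i] + (half - y[i]) * (t[i + 1] - t[i]) / (y[i + 1] - y[i])
    } else stats::median(t)
    t_half <- max(t_half, min(t[t > 0]), na.rm = TRUE)
    # fit in rescaled time u = t / t_half so the rate parameter is O(1):
    # on log-spaced second-spanning grids the raw-rate Jacobian column is
    # orders of magnitude smaller than the amplitude columns and trips the
    # singular-gradient check
    t_s <- t_half
    u <- t / t_s
    sw <- sqrt(w)
    if (model == "hill") {
      start <- list(base = y0g, amplitude = yIg - y0g, K = 1, n = 1)
      lower <- c(base = -Inf, amplitude = -Inf, K = .Machine$double.xmin, n = 1e-3)
      predict_u <- function(p) p$base + p$amplitude * u^p$n / (u^p$n + p$K^p$n)
    } else {
      start <- list(y0 = y0g, y_inf = yIg, k = 1)
      lower <- c(y0 = -Inf, y_inf = -Inf, k = .Machine$double.xmin)
      predict_u <- function(p) p$y_inf + (p$y0 - p$y_inf) * exp(-p$k * u)
    }
    res <- minpack.lm::nls.lm(
      par = start, lower = lower,
      fn = function(p) sw * (y - predict_u(p)),
      control = minpack.lm::nls.lm.control(maxiter = 500))
    if (res$info == 0 || res$info == 9 || !all(is.finite(unlist(res$par))))
      stop("kinetic fit did not converge: ", res$message,
           " (time scale ", sprintf("%.4g", t_s), " s; starting values: ",
           paste(names(start), sprintf("%.4g", unlist(start)),
                 sep = "=", collapse = ", "), ")", call. = FALSE)
    params <- res$par
    se <- tryCatch(summary(res)$coefficients[, "Std. Error"],
                   error = function(e) {
                     stats::setNames(rep(NA_real_, npar), names(start))
                   })
    stderr <- as.list(se)
    # map back to absolute time units
    if (model == "hill") {
      params$K <- params$K * t_s
      stderr$K <- stderr$K * t_s
    } else {
      params$k <- params$k / t_s
      stderr$k <- stderr$k / t_s
    }
    r2 <- NA_real_
  }
  pred <- .kin_model(model, params)
  rms <- sqrt(mean((y - pred(t))^2))
  structure(list(model = model, params = params, stderr = stderr,
                 fit_range = if (is.null(fit_range)) range(t) else fit_range,
                 n_points = length(t), rms = rms, r_squared = r2,
                 predict = pred),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit> model=%s, %d points, RMS %.4g\n",
              x$model, x$n_points, x$rms))
  for (nm in names(x$params))
    cat(sprintf("  %s = %.6g +- %.3g\n", nm, x$params[[nm]],
                if (is.null(x$stderr[[nm]])) NA else x$stderr[[nm]]))
  invisible(x)
}

#' Scale serial-mode series members to a conserved band
#'
#' In serial mode (one spectrum per crystal) the difference-peak height is
#' modulated by each crystal's thickness. Each member is rescaled so that
#' its conserved-band maximum equals the series median of those maxima,
#' making members comparable before band integration.
#'
#' @param series A [spectrum_series()].
#' @param conserved_band `c(lo, hi)` nm; every member must have a positive
#'   maximum there.
#' @return The rescaled series; each member's factor is in its history.
#' @export
scale_series_pairwise <- function(series, conserved_band) {
  stopifnot(inherits(series, "spectrum_series"))
  grid <- series$members[[1]]$wavelengths
  idx <- band_indices(grid, conserved_band)
  if (!length(idx)) stop("conserved_band does not intersect the grid")
  maxima <- vapply(series$members, function(m) {
    ok <- idx[!m$mask[idx]]
    if (!length(ok)) return(NA_real_)
    max(m$values[ok])
  }, numeric(1))
  if (anyNA(maxima) || any(maxima <= 0))
    stop("every member needs a positive conserved-band maximum")
  target <- stats::median(maxima)
  members <- lapply(seq_along(series$members), function(i) {
    m <- series$members[[i]]
    f <- target / maxima[i]
    m$values <- m$values * f
    add_history(m, "scale_series_pairwise",
                list(band = conserved_band, factor = f))
  })
  spectrum_series(members, axis = series$axis, labels = series$labels)
}
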