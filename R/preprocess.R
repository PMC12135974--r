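# Smoothing, peak scaling and difference-spectrum construction.

# mirror-pad a vector by k points on each side (no edge repetition);
# used by the derivative filter in the dent detector
.mirror_pad <- function(x, k) c(x[(k + 1):2], x, x[(length(x) - 1):(length(x) - k)])

# least-squares polynomial over the window, evaluated at offset 0
.local_polyfit_at <- function(offsets, vals, degree) {
  X <- outer(offsets, 0:degree, `^`)
  co <- tryCatch(qr.coef(qr(X), vals), error = function(e) NULL)
  if (is.null(co) || anyNA(co)) return(NA_real_)
  co[1]
}

# Shared smoother: degree = NULL gives a plain moving mean (windows shrink
# at the edges), degree = p gives Savitzky-Golay (edge points use the full
# first/last window asymmetrically, so polynomials of degree <= p are
# reproduced exactly everywhere). Windows containing masked points are
# re-fitted on the surviving points.
.smooth_core <- function(s, window, degree, op, params) {
  n <- length(s$values)
  if (window > n || (!is.null(degree) && window >= n))
    stop("window must be smaller than the spectrum length")
  k <- (window - 1) %/% 2
  vals <- s$values
  vals[s$mask] <- NA_real_
  out <- rep(NA_real_, n)
  out_mask <- rep(FALSE, n)
  # interior fast path via linear filtering with the centre-row weights
  if (is.null(degree)) {
    h <- rep(1 / window, window)
  } else {
    h <- signal::sgolay(p = degree, n = window)[k + 1, ]
  }
  sm <- stats::filter(vals, rev(h), sides = 2)
  any_mask <- any(s$mask)
  for (i in seq_len(n)) {
    interior <- i > k && i <= n - k
    win <- if (is.null(degree)) max(1, i - k):min(n, i + k)
           else if (i <= k) 1:window
           else if (i > n - k) (n - window + 1):n
           else (i - k):(i + k)
    win_masked <- any_mask && any(s$mask[win])
    if (interior && !win_masked && !is.na(sm[i])) {
      out[i] <- sm[i]
    } else {
      ok <- !s$mask[win]
      need <- if (is.null(degree)) 1L else degree + 2L
      if (sum(ok) >= need) {
        if (is.null(degree)) out[i] <- mean(vals[win][ok])
        else out[i] <- .local_polyfit_at((win - i)[ok], vals[win][ok], degree)
      }
      if (is.na(out[i])) out_mask[i] <- TRUE
    }
  }
  out[out_mask] <- NaN
  sp <- spectrum(s$wavelengths, out, kind = s$kind, label = s$label,
                 history = s$history, mask = out_mask)
  add_history(sp, op, params)
}

#' Savitzky-Golay smoothing
#'
#' Replaces every point by the centre value of the least-squares polynomial
#' of the given degree fitted over its window (the classic noise-removal
#' filter for spectra; the default is a third-degree polynomial over
#' 21-point windows). Edge points reuse the full first/last window with the
#' polynomial evaluated at their own position, so the spectrum is not
#' shortened and polynomials of degree <= `degree` on a uniform grid pass
#' through exactly. Windows containing masked points are re-fitted on the
#' remaining points when at least `degree + 2` survive, otherwise the
#' output point is masked.
#'
#' @param s A [spectrum()].
#' @param window Odd window length (> `degree`), default 21.
#' @param degree Polynomial degree, default 3.
#' @return Smoothed spectrum. Warns when the grid spacing varies by more
#'   than 5% (the filter assumes an approximately uniform grid).
#' @export
smooth_savgol <- function(s, window = 21, degree = 3) {
  stopifnot(inherits(s, "spectrum"))
  if (window %% 2 != 1) stop("window must be odd")
  if (window <= degree) stop("window must exceed the polynomial degree")
  dw <- diff(s$wavelengths)
  if (max(dw) / min(dw) > 1.05)
    warning("wavelength spacing varies by more than 5%; Savitzky-Golay assumes a uniform grid")
  .smooth_core(s, window, degree, "smooth_savgol",
               list(window = window, degree = degree))
}

#' Rolling-average smoothing
#'
#' Centred moving mean; windows shrink at the edges so the spectrum is not
#' shortened. Masked points are excluded from each window (a fully masked
#' window yields a masked point). Even windows are rounded up to the next
#' odd length so the filter stays centred.
#'
#' @param s A [spectrum()].
#' @param window Window length >= 1.
#' @return Smoothed spectrum; `window = 1` is the identity.
#' @export
smooth_rolling <- function(s, window = 5) {
  stopifnot(inherits(s, "spectrum"))
  if (window < 1) stop("window must be >= 1")
  if (window > length(s$values)) stop("window must not exceed the spectrum length")
  if (window == 1) return(add_history(s, "smooth_rolling", list(window = 1)))
  if (window %% 2 == 0) window <- window + 1
  n <- length(s$values)
  window <- min(window, if (n %% 2 == 1) n else n - 1)
  .smooth_core(s, window, NULL, "smooth_rolling", list(window = window))
}

#' Scale a spectrum to a conserved absorption peak
#'
#' Spectra from different crystals (or orientations) probe different optical
#' path lengths, so they are compared after scaling to a conserved peak:
#' the spectrum is multiplied by `target / max(values in peak_band)`. Use
#' `target = "unit"` for unit peak height. The band maximum (rather than a
#' single wavelength) is used for robustness to single-pixel noise; pass a
#' zero-width band `c(w, w)` for single-wavelength behaviour.
#'
#' @param s A [spectrum()], normally baseline-corrected first.
#' @param peak_band `c(lo, hi)` nm.
#' @param target Target peak value (OD), or `"unit"` for 1.
#' @return Scaled spectrum with the factor recorded in its history.
#' @export
scale_to_peak <- function(s, peak_band, target = "unit") {
  idx <- band_indices(s$wavelengths, peak_band)
  idx <- idx[!s$mask[idx]]
  if (!length(idx)) stop("peak_band contains no unmasked grid points")
  mx <- max(s$values[idx])
  if (mx <= 0)
    stop("non-positive band maximum; apply a baseline correction before scaling")
  if (identical(target, "unit")) target <- 1
  factor <- target / mx
  s$values <- s$values * factor
  add_history(s, "scale_to_peak",
              list(band = peak_band, target = target, factor = factor))
}

#' Light - dark difference series
#'
#' Subtracts a dark (ground-state) spectrum from every member, isolating
#' reaction-induced changes; masks are propagated as the union of the member
#' and dark masks.
#'
#' @param series A [spectrum_series()].
#' @param dark A [spectrum()] on the same grid, or a member index.
#' @return A difference [spectrum_series()] with the original labels.
#' @export
difference_series <- function(series, dark) {
  stopifnot(inherits(series, "spectrum_series"))
  if (is.numeric(dark) && length(dark) == 1) dark <- series$members[[dark]]
  stopifnot(inherits(dark, "spectrum"))
  grid <- series$members[[1]]$wavelengths
  if (length(dark$wavelengths) != length(grid) || !all(dark$wavelengths == grid))
    stop("dark spectrum must share the series grid")
  members <- lapply(series$members, function(m) {
    vals <- m$values - dark$values
    msk <- m$mask | dark$mask
    vals[msk] <- NaN
    sp <- spectrum(grid, vals, kind = m$kind, label = m$label,
                   history = m$history, mask = msk)
    add_history(sp, "difference", list(dark = format(dark$label)))
  })
  spectrum_series(members, axis = series$axis, labels = series$labels)
}
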