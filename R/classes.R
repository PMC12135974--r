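#' Raw detector trace
#'
#' A single spectrometer readout: a strictly increasing wavelength grid and
#' the photon counts recorded on it, together with its role in the absorbance
#' calculation (transmitted-through-sample, lamp reference, or dark
#' background).
#'
#' @param wavelengths Numeric vector of wavelengths in nm, strictly
#'   increasing, length >= 2.
#' @param counts Numeric vector of detector counts, same length as
#'   `wavelengths`.
#' @param role One of `"sample"`, `"reference"`, `"background"`.
#' @param integration_time Integration time in seconds, or `NA` if unknown.
#' @param detector_full_scale Detector full-scale count, or `NA` if unknown.
#' @param source_id Free-text provenance (file name, header lines).
#' @return An object of class `raw_trace`.
#' @export
raw_trace <- function(wavelengths, counts, role = c("sample", "reference", "background"),
                      integration_time = NA_real_, detector_full_scale = NA_real_,
                      source_id = "") {
  role <- match.arg(role)
  wavelengths <- as.numeric(wavelengths)
  counts <- as.numeric(counts)
  if (length(wavelengths) != length(counts))
    stop("wavelengths and counts must have the same length")
  if (length(wavelengths) < 2)
    stop("a trace needs at least 2 points")
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  structure(list(wavelengths = wavelengths, counts = counts, role = role,
                 integration_time = integration_time,
                 detector_full_scale = detector_full_scale,
                 source_id = source_id),
            class = "raw_trace")
}

#' Wavelength-indexed spectrum
#'
#' Holds absorbance (OD) or fluorescence values on a strictly increasing
#' wavelength grid, a label (time in seconds, dose, or free text), an
#' append-only history of applied corrections, and an optional mask marking
#' invalid points (`TRUE` = masked, e.g. removed laser-dent points or
#' non-physical transmission).
#'
#' @param wavelengths Numeric, nm, strictly increasing.
#' @param values Numeric, same length; `NA` allowed only where masked.
#' @param kind `"absorbance"` or `"fluorescence"`.
#' @param label Scalar time (s), dose, or character label.
#' @param history List of history records (see [add_history()]).
#' @param mask Logical vector, `TRUE` where the point is masked; `NULL`
#'   means no masked points.
#' @return An object of class `spectrum`.
#' @export
spectrum <- function(wavelengths, values, kind = c("absorbance", "fluorescence"),
                     label = NA, history = list(), mask = NULL) {
  kind <- match.arg(kind)
  wavelengths <- as.numeric(wavelengths)
  values <- as.numeric(values)
  if (length(wavelengths) != length(values))
    stop("wavelengths and values must have the same length")
  if (length(wavelengths) < 2)
    stop("a spectrum needs at least 2 points")
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (is.null(mask)) mask <- rep(FALSE, length(values))
  mask <- as.logical(mask) | !is.finite(values)
  if (length(mask) != length(values))
    stop("mask must have the same length as values")
  structure(list(wavelengths = wavelengths, values = values, kind = kind,
                 label = label, history = history, mask = mask),
            class = "spectrum")
}

#' Append an operation record to a spectrum's history
#'
#' @param s A `spectrum`.
#' @param op Operation name.
#' @param params Named list of parameters the operation used.
#' @return The spectrum with one more history entry.
#' @export
add_history <- function(s, op, params = list()) {
  s$history <- c(s$history, list(list(op = op, params = params)))
  s
}

#' Ordered series of spectra on a shared wavelength grid
#'
#' All members share one wavelength grid (resampling happens at
#' construction via [read_series()] or [simulate_series()], never silently
#' later). Labels are strictly increasing when the axis is time or dose.
#'
#' @param members List of `spectrum` objects on an identical grid.
#' @param axis `"time"`, `"dose"`, or `"index"`.
#' @param labels Numeric labels, one per member.
#' @return An object of class `spectrum_series`.
#' @export
spectrum_series <- function(members, axis = c("time", "dose", "index"),
                            labels = NULL) {
  axis <- match.arg(axis)
  if (length(members) < 1) stop("a series needs at least one member")
  if (!all(vapply(members, inherits, logical(1), "spectrum")))
    stop("all members must be spectrum objects")
  grid <- members[[1]]$wavelengths
  same <- vapply(members, function(m)
    length(m$wavelengths) == length(grid) && all(m$wavelengths == grid),
    logical(1))
  if (!all(same)) stop("all members must share an identical wavelength grid")
  if (is.null(labels)) {
    labels <- if (axis == "index") seq_along(members) else
      vapply(members, function(m) as.numeric(m$label), numeric(1))
  }
  labels <- as.numeric(labels)
  if (length(labels) != length(members))
    stop("one label per member required")
  if (axis %in% c("time", "dose")) {
    if (anyNA(labels)) stop("time/dose axis requires numeric labels")
    if (any(diff(labels) <= 0))
      stop("labels must be strictly increasing on a time/dose axis")
  }
  structure(list(members = members, axis = axis, labels = labels),
            class = "spectrum_series")
}

#' @export
length.spectrum_series <- function(x) length(x$members)

#' @export
print.raw_trace <- function(x, ...) {
  cat(sprintf("<raw_trace> role=%s, %d points, %.1f-%.1f nm\n",
              x$role, length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> kind=%s, %d points (%d masked), %.1f-%.1f nm, label=%s\n",
              x$kind, length(x$wavelengths), sum(x$mask),
              min(x$wavelengths), max(x$wavelengths),
              format(x$label)))
  if (length(x$history))
    cat("  history:", paste(vapply(x$history, `[[`, "", "op"), collapse = " -> "), "\n")
  invisible(x)
}

#' @export
print.spectrum_series <- function(x, ...) {
  cat(sprintf("<spectrum_series> %d members, axis=%s, %d wavelengths\n",
              length(x$members), x$axis, length(x$members[[1]]$wavelengths)))
  invisible(x)
}

# indices of grid points inside a closed [lo, hi] band
band_indices <- function(wavelengths, band) {
  if (length(band) != 2 || band[2] < band[1])
    stop("band must be c(lo, hi) with hi >= lo")
  which(wavelengths >= band[1] & wavelengths <= band[2])
}

clip01 <- function(x) pmin(1, pmax(0, x))
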