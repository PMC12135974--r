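# Absorbance from raw traces and photon-count confidence scoring.

.resample_trace <- function(tr, grid) {
  if (length(tr$wavelengths) == length(grid) && all(tr$wavelengths == grid))
    return(tr)
  cts <- stats::approx(tr$wavelengths, tr$counts, xout = grid, rule = 1)$y
  if (anyNA(cts)) stop("trace ", tr$role, " does not cover the sample grid")
  raw_trace(grid, cts, role = tr$role,
            integration_time = tr$integration_time,
            detector_full_scale = tr$detector_full_scale,
            source_id = tr$source_id)
}

#' Compute absorbance from sample, reference and background traces
#'
#' Absorbance per wavelength is
#' \deqn{A(\lambda) = -\log_{10}\frac{I_{sample}(\lambda) - I_{background}(\lambda)}
#'                                  {I_{reference}(\lambda) - I_{background}(\lambda)}}
#' Reference and background are resampled onto the sample grid if needed.
#' Points where either net count (numerator or denominator) is non-positive
#' are masked rather than clamped: a non-positive net count carries no
#' transmission information, and masking keeps the wavelength grid intact
#' for downstream series operations.
#'
#' @param sample,reference,background [raw_trace()] objects.
#' @param label Label for the resulting spectrum.
#' @return An absorbance [spectrum()] with the operation recorded in its
#'   history.
#' @export
compute_absorbance <- function(sample, reference, background, label = NA) {
  stopifnot(inherits(sample, "raw_trace"), inherits(reference, "raw_trace"),
            inherits(background, "raw_trace"))
  grid <- sample$wavelengths
  reference <- .resample_trace(reference, grid)
  background <- .resample_trace(background, grid)
  num <- sample$counts - background$counts
  den <- reference$counts - background$counts
  bad <- !(num > 0 & den > 0)
  a <- rep(NaN, length(grid))
  a[!bad] <- -log10(num[!bad] / den[!bad])
  if (all(bad)) stop("no valid transmission: all points masked")
  s <- spectrum(grid, a, kind = "absorbance", label = label, mask = bad)
  add_history(s, "compute_absorbance",
              list(n_masked = sum(bad), sample = sample$source_id))
}

#' Flag detector-saturation plateaus in a raw trace
#'
#' A point is flagged iff it belongs to a run of at least `run_length`
#' consecutive points all within `tol` counts of the detector full scale
#' (plateauing at the maximum of the detector dynamic range).
#'
#' @param trace A [raw_trace()].
#' @param full_scale Full-scale count, or `"auto"` to use the trace maximum.
#' @param run_length Minimum plateau length (>= 2).
#' @param tol Count tolerance around full scale (>= 0).
#' @return Logical vector of per-point saturation flags.
#' @export
detect_saturation <- function(trace, full_scale = "auto", run_length = 3, tol = 0) {
  stopifnot(inherits(trace, "raw_trace"))
  if (tol < 0) stop("tol must be >= 0")
  if (run_length < 2) stop("run_length must be >= 2")
  if (identical(full_scale, "auto"))
    full_scale <- if (is.finite(trace$detector_full_scale)) trace$detector_full_scale
                  else max(trace$counts)
  near <- trace$counts >= full_scale - tol
  r <- rle(near)
  keep <- r$values & r$lengths >= run_length
  inverse.rle(list(values = keep, lengths = r$lengths))
}

#' Per-wavelength confidence from photon counts
#'
#' Scores how trustworthy each absorbance point is, given that the
#' signal-to-noise ratio collapses where either the sample or the reference
#' trace has critically low or saturated photon counts. Per trace the score
#' is a clipped linear ramp on background-subtracted counts,
#' `clip((I - I_bg - low) / ramp, 0, 1)`, set to 0 where that trace is
#' saturated; the profile score is the pointwise minimum over the sample and
#' reference scores. Saturation of either trace therefore zeroes the score
#' (whether the original tool considers one or both traces is not specified;
#' either-trace is the conservative choice).
#'
#' @param sample,reference,background [raw_trace()] objects on one grid.
#' @param low Counts below which (net of background) the score is 0.
#'   Default: 2% of full scale.
#' @param ramp Count range over which the score ramps 0 to 1. Default: 8%
#'   of full scale.
#' @param full_scale Detector full scale, or `"auto"`.
#' @param run_length,tol Saturation-run parameters, see
#'   [detect_saturation()]; `tol` defaults to 0.5% of full scale.
#' @return A `confidence_profile` object: wavelengths, `score` in \[0,1\],
#'   `low_count_flag` and `saturated_flag` (either trace), and the
#'   thresholds used.
#' @export
confidence_profile <- function(sample, reference, background,
                               low = NULL, ramp = NULL, full_scale = "auto",
                               run_length = 3, tol = NULL) {
  grid <- sample$wavelengths
  reference <- .resample_trace(reference, grid)
  background <- .resample_trace(background, grid)
  if (identical(full_scale, "auto"))
    full_scale <- if (is.finite(sample$detector_full_scale)) sample$detector_full_scale
                  else max(c(sample$counts, reference$counts))
  if (is.null(low)) low <- 0.02 * full_scale
  if (is.null(ramp)) ramp <- 0.08 * full_scale
  if (is.null(tol)) tol <- 0.005 * full_scale
  if (ramp <= 0) stop("ramp must be > 0")
  sat_s <- detect_saturation(sample, full_scale, run_length, tol)
  sat_r <- detect_saturation(reference, full_scale, run_length, tol)
  score_one <- function(tr, sat) {
    s <- clip01((tr$counts - background$counts - low) / ramp)
    s[sat] <- 0
    s
  }
  s_sample <- score_one(sample, sat_s)
  s_ref <- score_one(reference, sat_r)
  structure(list(wavelengths = grid,
                 score = pmin(s_sample, s_ref),
                 low_count_flag = (sample$counts - background$counts <= low) |
                                  (reference$counts - background$counts <= low),
                 saturated_flag = sat_s | sat_r,
                 thresholds = list(low = low, ramp = ramp,
                                   full_scale = full_scale, tol = tol,
                                   run_length = run_length)),
            class = "confidence_profile")
}

#' @export
print.confidence_profile <- function(x, ...) {
  cat(sprintf("<confidence_profile> %d points, %d low-count, %d saturated, mean score %.3f\n",
              length(x$score), sum(x$low_count_flag), sum(x$saturated_flag),
              mean(x$score)))
  invisible(x)
}
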