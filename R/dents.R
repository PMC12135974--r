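# Detection and removal of the nanosecond-laser "dent": the tail of the
# actinic laser pulse reaching the spectrometer during integration shows up
# as a spurious negative dip in the absorbance spectrum. Dips are located
# from local minima of the spectrum; their boundaries come from the second
# derivative (Savitzky-Golay differentiation): the curvature shoulders
# flanking a dip are local minima of the second derivative, and the dip is
# considered ended where the curvature returns to zero. Because for an
# isolated Gaussian dip on a gently varying background the second
# derivative approaches zero without crossing it, "zero" is taken with a
# relative tolerance (5% of the shoulder magnitude), which also keeps the
# gentle curvature of a broad underlying absorption band from being
# mistaken for the dent's own.

.local_minima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] < x[1:(n - 2)] & x[2:(n - 1)] <= x[3:n]) + 1L
}

# second derivative in index units via Savitzky-Golay differentiation
.sg_deriv2 <- function(vals, window, degree = 3) {
  n <- length(vals)
  if (window %% 2 == 0) window <- window + 1
  window <- min(window, if (n %% 2 == 1) n - 2 else n - 1)
  if (window < degree + 2) window <- degree + 2 + (degree %% 2)
  k <- (window - 1) %/% 2
  offs <- -k:k
  X <- outer(offs, 0:degree, `^`)
  # row of the pseudo-inverse giving the 2nd-order coefficient, times 2
  P <- solve(t(X) %*% X, t(X))
  h <- 2 * P[3, ]
  xp <- .mirror_pad(vals, k)
  as.numeric(stats::filter(xp, rev(h), sides = 2))[(k + 1):(k + n)]
}

# boundary search: walk outward from a dip bottom, through the curvature
# shoulder, to the tolerance-crossed zero of the second derivative; a local
# maximum of the spectrum is a hard stop.
.walk_boundary <- function(y, d2, i, step, rel_tol = 0.05) {
  n <- length(y)
  j <- i + step
  shoulder <- NA_real_
  last <- i
  while (j >= 2 && j <= n - 1) {
    if (y[j] > y[j - 1] && y[j] >= y[j + 1]) return(j)  # local max of y
    if (is.na(shoulder)) {
      if (d2[j] < 0 && d2[j] <= d2[j - 1] && d2[j] <= d2[j + 1])
        shoulder <- abs(d2[j])
    } else if (d2[j] >= -rel_tol * shoulder) {
      return(j)
    }
    last <- j
    j <- j + step
  }
  if (j < 1) 1L else if (j > n) n else j
}

#' Detect absorption dips and the laser dent
#'
#' Finds local minima of the (lightly smoothed) absorbance spectrum, derives
#' each dip's boundaries from the second derivative, and measures its
#' amplitude as the depth from the straight line joining the boundary
#' flanks down to the minimum. Dips with amplitude below `min_prominence`
#' are discarded. The largest-amplitude dip is the main (laser) dent; all
#' others are catalogued as minor dips. Amplitude ties break toward the
#' shorter wavelength.
#'
#' @param s A [spectrum()].
#' @param min_prominence Minimum dip amplitude (OD). Default: 5 times the
#'   robust noise level (median absolute deviation of the first
#'   differences, scaled), with a floor of 1e-3 OD.
#' @param smooth_window Savitzky-Golay window for the detection smoothing
#'   and differentiation (default 11).
#' @return A `dent_mask`: `main_dent` (interval nm, centre nm, amplitude OD,
#'   `removed_indices`), and `minor_dips` (data frame of centre and
#'   amplitude). `main_dent` is `NULL` when no dip clears the prominence
#'   threshold (an empty mask, not an error).
#' @export
detect_dents <- function(s, min_prominence = NULL, smooth_window = 11) {
  stopifnot(inherits(s, "spectrum"))
  n <- length(s$values)
  if (n <= smooth_window) stop("spectrum shorter than smooth_window")
  y <- s$values
  if (any(s$mask)) {  # work on an interpolated copy so indexing stays global
    ok <- !s$mask
    y <- stats::approx(s$wavelengths[ok], y[ok], xout = s$wavelengths, rule = 2)$y
  }
  ys <- .smooth_core(spectrum(s$wavelengths, y), .odd(smooth_window),
                     3, "smooth", list())$values
  d2 <- .sg_deriv2(ys, smooth_window)
  if (is.null(min_prominence)) {
    sigma <- stats::mad(diff(s$values[!s$mask])) / sqrt(2)
    min_prominence <- max(5 * sigma, 1e-3)
  }
  cand <- .local_minima(ys)
  cand <- cand[d2[cand] > 0]  # a dip bottom is convex
  dips <- list()
  for (i in cand) {
    lo <- .walk_boundary(ys, d2, i, -1L)
    hi <- .walk_boundary(ys, d2, i, +1L)
    if (hi - lo < 2) next
    # depth from the interpolated flanks to the minimum
    chord <- ys[lo] + (ys[hi] - ys[lo]) * (i - lo) / (hi - lo)
    amp <- chord - ys[i]
    if (amp >= min_prominence)
      dips[[length(dips) + 1]] <- list(centre_idx = i, lo = lo, hi = hi, amplitude = amp)
  }
  if (!length(dips)) {
    empty_df <- data.frame(centre = numeric(0), amplitude = numeric(0))
    return(structure(list(main_dent = NULL, minor_dips = empty_df,
                          dips = cbind(empty_df, lo_idx = numeric(0),
                                       hi_idx = numeric(0)),
                          min_prominence = min_prominence),
                     class = "dent_mask"))
  }
  amps <- vapply(dips, `[[`, numeric(1), "amplitude")
  centres <- vapply(dips, `[[`, numeric(1), "centre_idx")
  main_i <- order(-amps, centres)[1]
  main <- dips[[main_i]]
  minor <- dips[-main_i]
  all_dips <- data.frame(
    centre = s$wavelengths[centres],
    amplitude = amps,
    lo_idx = vapply(dips, `[[`, numeric(1), "lo"),
    hi_idx = vapply(dips, `[[`, numeric(1), "hi"))
  structure(list(
    main_dent = list(interval = s$wavelengths[c(main$lo, main$hi)],
                     centre = s$wavelengths[main$centre_idx],
                     amplitude = main$amplitude,
                     removed_indices = main$lo:main$hi),
    minor_dips = data.frame(
      centre = s$wavelengths[vapply(minor, `[[`, numeric(1), "centre_idx")],
      amplitude = vapply(minor, `[[`, numeric(1), "amplitude")),
    dips = all_dips,
    min_prominence = min_prominence),
    class = "dent_mask")
}

.odd <- function(w) if (w %% 2 == 1) w else w + 1

#' @export
print.dent_mask <- function(x, ...) {
  if (is.null(x$main_dent)) cat("<dent_mask> empty\n")
  else cat(sprintf("<dent_mask> main dent %.1f nm [%.1f, %.1f], %.3g OD; %d minor dip(s)\n",
                   x$main_dent$centre, x$main_dent$interval[1], x$main_dent$interval[2],
                   x$main_dent$amplitude, nrow(x$minor_dips)))
  invisible(x)
}

# apply a dent interval to one spectrum
.apply_dent <- function(s, idx, fill) {
  if (fill == "mask") {
    s$values[idx] <- NaN
    s$mask[idx] <- TRUE
  } else {
    lo <- min(idx); hi <- max(idx)
    x0 <- max(1, lo - 1); x1 <- min(length(s$values), hi + 1)
    s$values[idx] <- stats::approx(s$wavelengths[c(x0, x1)], s$values[c(x0, x1)],
                                   xout = s$wavelengths[idx])$y
  }
  add_history(s, "remove_laser_dent",
              list(lo = s$wavelengths[min(idx)], hi = s$wavelengths[max(idx)],
                   fill = fill))
}

#' Remove the laser dent across a kinetic series
#'
#' The dent is detected on the first member (or taken from a supplied
#' template mask); for every subsequent member only the main dip inside the
#' first member's dent interval, widened by `smooth_window` grid points on
#' each side, is searched for — the laser wavelength is fixed, so the dent
#' can only drift slightly. Members with no detectable dip inside the
#' search window have the template interval removed. Removed points are
#' either masked or bridged by linear interpolation.
#'
#' @param series A [spectrum_series()].
#' @param template Optional `dent_mask` to use instead of detecting on the
#'   first member.
#' @param fill `"mask"` or `"interpolate"`.
#' @param min_prominence,smooth_window Passed to [detect_dents()].
#' @return A list: `series` (corrected) and `masks` (one `dent_mask` per
#'   member). When no dent is found on the first member the series is
#'   returned unchanged with empty masks.
#' @export
remove_laser_dent <- function(series, template = NULL,
                              fill = c("mask", "interpolate"),
                              min_prominence = NULL, smooth_window = 11) {
  fill <- match.arg(fill)
  stopifnot(inherits(series, "spectrum_series"))
  grid <- series$members[[1]]$wavelengths
  first_mask <- if (!is.null(template)) template
    else detect_dents(series$members[[1]], min_prominence, smooth_window)
  if (is.null(first_mask$main_dent)) {
    empty <- lapply(series$members, function(m) first_mask)
    return(list(series = series, masks = empty))
  }
  tpl_idx <- which(grid >= first_mask$main_dent$interval[1] &
                   grid <= first_mask$main_dent$interval[2])
  win_lo <- max(1, min(tpl_idx) - smooth_window)
  win_hi <- min(length(grid), max(tpl_idx) + smooth_window)
  masks <- vector("list", length(series$members))
  members <- series$members
  for (i in seq_along(members)) {
    if (i == 1 && is.null(template)) {
      dm <- first_mask
      idx <- dm$main_dent$removed_indices
    } else {
      # for later time points only the main dip inside the window counts
      dm_all <- detect_dents(members[[i]], min_prominence, smooth_window)
      idx <- NULL
      dm <- first_mask
      if (!is.null(dm_all$main_dent) && nrow(dm_all$dips)) {
        d <- dm_all$dips
        inwin <- d$centre >= grid[win_lo] & d$centre <= grid[win_hi]
        if (any(inwin)) {
          d <- d[inwin, , drop = FALSE]
          best <- d[order(-d$amplitude, d$centre)[1], ]
          idx <- max(win_lo, best$lo_idx):min(win_hi, best$hi_idx)
          dm <- dm_all
          dm$main_dent <- list(interval = grid[range(idx)],
                               centre = best$centre,
                               amplitude = best$amplitude,
                               removed_indices = idx)
        }
      }
      if (is.null(idx)) {  # nothing found: remove the template interval
        idx <- tpl_idx
        dm$main_dent$removed_indices <- idx
      }
    }
    members[[i]] <- .apply_dent(members[[i]], idx, fill)
    masks[[i]] <- dm
  }
  list(series = spectrum_series(members, axis = series$axis, labels = series$labels),
       masks = masks)
}
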