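# Singular value decomposition of a series of (difference) spectra.
#
# The observed spectra are stacked as rows of a matrix A in chronological
# order (traditionally light - dark difference spectra, so unchanging
# features cancel). A = U S V^T decomposes the series into time-invariant
# basis spectra (columns of V mapped to wavelength: the left singular
# vectors, lSV), their weights (singular values), and the time course of
# each basis spectrum (right singular vectors, rSV). With rows = time and
# columns = wavelength, the wavelength-side vectors come from V and the
# time-side vectors from U; they are exposed under the spectroscopic names
# lSV (wavelength x component) and rSV (time x component).

#' Build the difference matrix for SVD
#'
#' Stacks the series members as rows ordered by ascending label, after
#' subtracting a dark spectrum. Masked points are handled by the chosen
#' policy: `"interpolate"` fills each row linearly across its masked
#' points; `"drop"` removes wavelength columns that are masked in every
#' row, and errors on columns masked in only some rows (those cannot be
#' dropped consistently).
#'
#' @param series A [spectrum_series()].
#' @param dark A [spectrum()], a member index, or `NULL` for no
#'   subtraction (already-differenced series).
#' @param mask_policy `"interpolate"` or `"drop"`.
#' @return A numeric matrix (time x wavelength) with `wavelengths` and
#'   `labels` attributes.
#' @export
build_difference_matrix <- function(series, dark = NULL,
                                    mask_policy = c("interpolate", "drop")) {
  mask_policy <- match.arg(mask_policy)
  stopifnot(inherits(series, "spectrum_series"))
  if (!is.null(dark)) series <- difference_series(series, dark)
  grid <- series$members[[1]]$wavelengths
  rows <- lapply(series$members, function(m) {
    v <- m$values
    v[m$mask] <- NA_real_
    v
  })
  A <- do.call(rbind, rows)
  if (anyNA(A)) {
    if (mask_policy == "interpolate") {
      for (i in seq_len(nrow(A))) {
        ok <- !is.na(A[i, ])
        if (sum(ok) < 2) stop("row ", i, " has too few unmasked points")
        A[i, ] <- stats::approx(grid[ok], A[i, ok], xout = grid, rule = 2)$y
      }
    } else {
      col_na <- colSums(is.na(A))
      partial <- which(col_na > 0 & col_na < nrow(A))
      if (length(partial))
        stop("columns masked in only some rows cannot be dropped consistently: wavelength ",
             paste(sprintf("%.6g", grid[utils::head(partial, 5)]), collapse = ", "))
      keep <- col_na == 0
      A <- A[, keep, drop = FALSE]
      grid <- grid[keep]
    }
  }
  attr(A, "wavelengths") <- grid
  attr(A, "labels") <- series$labels
  A
}

#' Singular value decomposition of a spectra matrix
#'
#' Thin SVD with a fixed sign convention: each wavelength-side basis
#' spectrum (lSV column) is flipped so that its maximum-magnitude element
#' is positive, with the matching time course (rSV column) flipped
#' accordingly; SVD signs are otherwise arbitrary. Explained variance per
#' component is \eqn{S_i^2 / \sum_j S_j^2}.
#'
#' @param A Matrix from [build_difference_matrix()] (rows = time).
#' @param n_components Number of components to keep, or `NULL` for all.
#' @return An `svd_result`: `lSV` (wavelength x component, orthonormal
#'   columns), `singular_values` (non-increasing), `rSV` (time x component,
#'   orthonormal columns), `explained_variance`, `wavelengths`, `labels`,
#'   `input_shape`.
#' @export
svd_decompose <- function(A, n_components = NULL) {
  if (!is.matrix(A) || !length(A)) stop("A must be a non-empty matrix")
  dec <- svd(A)
  # rows are time, columns wavelength: U is time-side, V wavelength-side
  lSV <- dec$v
  rSV <- dec$u
  s <- dec$d
  for (j in seq_along(s)) {
    i <- which.max(abs(lSV[, j]))
    if (lSV[i, j] < 0) {
      lSV[, j] <- -lSV[, j]
      rSV[, j] <- -rSV[, j]
    }
  }
  ev <- if (sum(s^2) > 0) s^2 / sum(s^2) else rep(0, length(s))
  k <- if (is.null(n_components)) length(s) else min(n_components, length(s))
  structure(list(lSV = lSV[, seq_len(k), drop = FALSE],
                 singular_values = s[seq_len(k)],
                 rSV = rSV[, seq_len(k), drop = FALSE],
                 explained_variance = ev[seq_len(k)],
                 wavelengths = attr(A, "wavelengths"),
                 labels = attr(A, "labels"),
                 input_shape = dim(A)),
            class = "svd_result")
}

#' @export
print.svd_result <- function(x, ...) {
  cat(sprintf("<svd_result> %d x %d input, %d component(s)\n",
              x$input_shape[1], x$input_shape[2], length(x$singular_values)))
  k <- min(5, length(x$singular_values))
  cat("  singular values:", sprintf("%.4g", x$singular_values[1:k]), "\n")
  cat("  explained variance:", sprintf("%.3f", x$explained_variance[1:k]), "\n")
  invisible(x)
}

#' Fit a kinetic model to one SVD time course
#'
#' Delegates to [fit_kinetic()] on the chosen rSV column against the series
#' labels; the linear model is available for drift components (e.g. slow
#' crystal displacement during data collection).
#'
#' @param result An `svd_result` carrying `labels`.
#' @param component 1-based component index.
#' @param model Passed to [fit_kinetic()].
#' @param ... Passed to [fit_kinetic()].
#' @return A `kinetic_fit`.
#' @export
component_kinetics <- function(result, component = 1,
                               model = c("exp_decay", "exp_rise", "hill", "linear"),
                               ...) {
  stopifnot(inherits(result, "svd_result"))
  if (component > ncol(result$rSV)) stop("component exceeds the decomposition rank")
  if (is.null(result$labels)) stop("the decomposition carries no time labels")
  trace <- list(times = result$labels, values = result$rSV[, component])
  fit_kinetic(trace, model = match.arg(model), ...)
}

#' Export an SVD result as three ASCII tables
#'
#' Writes `<prefix>_lsv.txt` (wavelength + one column per basis spectrum),
#' `<prefix>_s.txt` (singular values and explained variance) and
#' `<prefix>_rsv.txt` (label + one column per time course).
#'
#' @param result An `svd_result`.
#' @param prefix Output path prefix.
#' @return Paths written, invisibly.
#' @export
write_svd_result <- function(result, prefix) {
  fmt_row <- function(...) paste(sprintf("%.12g", c(...)), collapse = " ")
  wpath <- paste0(prefix, "_lsv.txt")
  spath <- paste0(prefix, "_s.txt")
  rpath <- paste0(prefix, "_rsv.txt")
  wl <- result$wavelengths
  if (is.null(wl)) wl <- seq_len(nrow(result$lSV))
  lab <- result$labels
  if (is.null(lab)) lab <- seq_len(nrow(result$rSV))
  write_ascii <- function(path, header, rows) {
    con <- file(path, open = "wb"); on.exit(close(con))
    writeLines(c(header, rows), con, sep = "\n")
  }
  write_ascii(wpath, "# xtalspec lSV: wavelength then one column per component",
              vapply(seq_along(wl), function(i) fmt_row(wl[i], result$lSV[i, ]), character(1)))
  write_ascii(spath, "# xtalspec singular values: value explained_variance",
              vapply(seq_along(result$singular_values), function(i)
                fmt_row(result$singular_values[i], result$explained_variance[i]),
                character(1)))
  write_ascii(rpath, "# xtalspec rSV: label then one column per component",
              vapply(seq_along(lab), function(i) fmt_row(lab[i], result$rSV[i, ]), character(1)))
  invisible(c(wpath, spath, rpath))
}
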