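# ASCII spectrum I/O: delimiter-flexible two-column exports as produced by
# fibre spectrometer software, with optional non-numeric header lines.

# Normalise one data line to whitespace-separated tokens with "." decimals.
# Tabs and semicolons always separate; a comma separates unless the line
# already splits into >= 2 whitespace tokens, in which case it is read as a
# decimal comma.
.normalise_line <- function(line) {
  line <- gsub("[\t;]", " ", line)
  if (grepl(",", line)) {
    toks <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(toks) >= 2) line <- gsub(",", ".", line)
    else line <- gsub(",", " ", line)
  }
  line
}

.parse_ascii_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  header <- character(0)
  rows <- list()
  for (line in lines) {
    norm <- .normalise_line(line)
    toks <- strsplit(trimws(norm), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(ifelse(tolower(toks) == "nan", "NaN", toks)))
    if (length(vals) >= 2 && !is.na(vals[1])) {
      rows[[length(rows) + 1L]] <- vals[1:2]
    } else if (length(rows) == 0L) {
      header <- c(header, line)
    }
  }
  if (length(rows) < 2)
    stop("format error: fewer than 2 numeric rows in ", path)
  m <- do.call(rbind, rows)
  list(wavelengths = m[, 1], values = m[, 2], header = header)
}

#' Read a spectrometer ASCII export
#'
#' Reads a two-column wavelength/value table. Delimiters (whitespace, tab,
#' comma, semicolon) and leading non-numeric header lines are sniffed;
#' decimal commas are accepted when unambiguous. Rows are sorted by
#' wavelength; duplicate wavelengths are an error (they indicate a corrupted
#' export, and are reported rather than averaged).
#'
#' @param path File path.
#' @param dialect `"two_column"`, `"headered"`, or `"auto"` (all three share
#'   the same sniffing parser; the value is recorded for provenance).
#' @param as `"auto"` (counts if any value exceeds 100, absorbance
#'   otherwise), `"absorbance"`, `"counts"`, or `"fluorescence"`.
#' @param role Trace role used when the file is read as counts.
#' @param label Label attached when the file is read as a spectrum.
#' @return A [raw_trace()] when read as counts, otherwise a [spectrum()].
#'   Header lines (and any `# key: value` metadata written by
#'   [write_spectrum()]) are preserved in `source_id`.
#' @export
read_trace <- function(path, dialect = c("auto", "two_column", "headered"),
                       as = c("auto", "absorbance", "counts", "fluorescence"),
                       role = "sample", label = NA) {
  dialect <- match.arg(dialect)
  as <- match.arg(as)
  if (!file.exists(path)) stop("cannot read file: ", path)
  tab <- .parse_ascii_table(path)
  ord <- order(tab$wavelengths)
  wl <- tab$wavelengths[ord]
  vals <- tab$values[ord]
  dup <- which(diff(wl) == 0)
  if (length(dup))
    stop(sprintf("format error: duplicate wavelength %.6g nm in %s", wl[dup[1]], path))
  source_id <- paste(c(basename(path), tab$header), collapse = "\n")
  if (as == "auto")
    as <- if (any(is.finite(vals) & vals > 100)) "counts" else "absorbance"
  if (as == "counts") {
    raw_trace(wl, vals, role = role, source_id = source_id)
  } else {
    if (is.na(label)) label <- .label_from_meta(tab$header, path)
    spectrum(wl, vals, kind = if (as == "fluorescence") "fluorescence" else "absorbance",
             label = label, history = list(), mask = NULL)
  }
}

.label_from_meta <- function(header, path) {
  hit <- grep("^#\\s*label:", header, value = TRUE)
  if (length(hit)) {
    lab <- trimws(sub("^#\\s*label:", "", hit[1]))
    num <- suppressWarnings(as.numeric(lab))
    if (!is.na(num)) return(num)
    if (nzchar(lab) && lab != "NA") return(lab)
  }
  NA
}

#' Write a spectrum to two-column ASCII
#'
#' Writes full-precision wavelength/value pairs, one per line, preceded by
#' `#`-prefixed header lines carrying the kind, label and correction history
#' so that the file round-trips through [read_trace()]. Masked points are
#' written with the sentinel value `nan`.
#'
#' @param s A [spectrum()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "spectrum"))
  vals <- ifelse(s$mask, "nan", sprintf("%.12g", s$values))
  hist_str <- vapply(s$history, function(h) {
    ps <- if (length(h$params))
      paste(names(h$params), vapply(h$params, function(p) paste(format(p), collapse = ","),
                                    character(1)), sep = "=", collapse = ", ")
    else ""
    paste0(h$op, "(", ps, ")")
  }, character(1))
  header <- c("# xtalspec spectrum",
              paste0("# kind: ", s$kind),
              paste0("# label: ", format(s$label)),
              if (length(hist_str)) paste0("# history: ", paste(hist_str, collapse = "; ")))
  body <- paste(sprintf("%.12g", s$wavelengths), vals)
  con <- file(path, open = "wb")  # fixed \n line endings for reproducibility
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n")
  invisible(path)
}

# Resample a spectrum onto a new grid by linear interpolation; masked source
# points are dropped before interpolation and grid points that cannot be
# interpolated become masked.
resample_spectrum <- function(s, grid) {
  ok <- !s$mask
  if (sum(ok) < 2) stop("too few unmasked points to resample")
  out <- stats::approx(s$wavelengths[ok], s$values[ok], xout = grid, rule = 1)$y
  sp <- spectrum(grid, ifelse(is.na(out), NaN, out), kind = s$kind,
                 label = s$label, history = s$history, mask = is.na(out))
  add_history(sp, "resample", list(n = length(grid),
                                   lo = min(grid), hi = max(grid)))
}

#' Parse a time/dose label from a file name
#'
#' Takes the last number in the file stem together with an optional unit
#' suffix: `us` (microseconds), `ms` (milliseconds), `s` (seconds), `Gy`
#' (gray). `t_000003us.txt` parses to `3e-6`.
#'
#' @param path File path or name.
#' @return Numeric label in seconds (or Gy), `NA` if no number is found.
#' @export
label_from_filename <- function(path) {
  stem <- tools::file_path_sans_ext(basename(path))
  m <- gregexpr("[0-9]+(?:\\.[0-9]+)?(?:e-?[0-9]+)?\\s*(us|ms|s|Gy)?", stem)[[1]]
  if (m[1] == -1) return(NA_real_)
  piece <- regmatches(stem, list(m))[[1]]
  piece <- piece[length(piece)]
  unit <- sub("^[0-9.e-]*", "", piece)
  num <- as.numeric(sub("(us|ms|s|Gy)$", "", piece))
  mult <- switch(unit, us = 1e-6, ms = 1e-3, s = 1, Gy = 1, 1)
  num * mult
}

#' Read a series of spectrum files onto a common grid
#'
#' Members are resampled by linear interpolation onto the first member's
#' grid restricted to the intersection of all wavelength ranges, then sorted
#' by ascending label. The common grid is therefore independent of the input
#' file order for time/dose axes.
#'
#' @param paths Character vector of file paths (or a glob pattern when
#'   `length(paths) == 1` and it contains a wildcard).
#' @param label_rule `"filename_number"` ([label_from_filename()] per file),
#'   `"manifest"` (two-column path/label file given in `manifest`), or
#'   `"explicit"` (numeric `labels` argument).
#' @param axis `"time"`, `"dose"`, or `"index"`.
#' @param labels Numeric labels when `label_rule = "explicit"`.
#' @param manifest Path to a manifest file when `label_rule = "manifest"`.
#' @param ... Passed on to [read_trace()].
#' @return A [spectrum_series()]. The original file order is recorded in
#'   each member's history.
#' @export
read_series <- function(paths, label_rule = c("filename_number", "manifest", "explicit"),
                        axis = c("time", "dose", "index"), labels = NULL,
                        manifest = NULL, ...) {
  label_rule <- match.arg(label_rule)
  axis <- match.arg(axis)
  if (length(paths) == 1 && grepl("[*?]", paths))
    paths <- Sys.glob(paths)
  if (length(paths) < 1) stop("no input files")
  if (label_rule == "manifest") {
    if (is.null(manifest)) stop("manifest path required")
    man <- utils::read.table(manifest, header = FALSE, sep = "",
                             col.names = c("path", "label"),
                             stringsAsFactors = FALSE)
    labels <- man$label[match(basename(paths), basename(man$path))]
    if (anyNA(labels)) stop("manifest does not cover all files")
  } else if (label_rule == "filename_number" && axis != "index") {
    labels <- vapply(paths, label_from_filename, numeric(1))
    if (anyNA(labels)) stop("could not parse a numeric label from every filename")
  } else if (label_rule == "explicit") {
    if (is.null(labels) || length(labels) != length(paths))
      stop("explicit labels must match the number of files")
  }
  if (axis == "index" || is.null(labels)) labels <- seq_along(paths)
  members <- lapply(seq_along(paths), function(i) {
    s <- read_trace(paths[i], ..., label = labels[i])
    if (!inherits(s, "spectrum"))
      stop("series members must be spectra (absorbance/fluorescence), got counts: ", paths[i])
    add_history(s, "read_series", list(file = basename(paths[i]), input_position = i))
  })
  build_series(members, axis = axis, labels = labels)
}

# Shared-grid series construction from arbitrary-grid members: intersect
# ranges, resample onto the (label-sorted) first member's grid, sort labels.
build_series <- function(members, axis, labels) {
  if (axis %in% c("time", "dose")) {
    if (anyNA(labels)) stop("numeric labels required for a ", axis, " axis")
    dup <- unique(labels[duplicated(labels)])
    if (length(dup))
      stop("duplicate labels: ", paste(format(dup), collapse = ", "))
    ord <- order(labels)
  } else ord <- seq_along(members)
  members <- members[ord]
  labels <- labels[ord]
  lo <- max(vapply(members, function(m) min(m$wavelengths), numeric(1)))
  hi <- min(vapply(members, function(m) max(m$wavelengths), numeric(1)))
  if (lo >= hi) stop("disjoint wavelength ranges across series members")
  grid <- members[[1]]$wavelengths
  grid <- grid[grid >= lo & grid <= hi]
  if (length(grid) < 2) stop("common wavelength range too narrow")
  members <- lapply(members, function(m) {
    if (length(m$wavelengths) == length(grid) && all(m$wavelengths == grid)) m
    else resample_spectrum(m, grid)
  })
  for (i in seq_along(members)) members[[i]]$label <- labels[i]
  spectrum_series(members, axis = axis, labels = labels)
}

#' Write every member of a series
#'
#' File names are `<prefix><index>.txt` with a zero-padded three-digit
#' index; the member label is carried in the file header.
#'
#' @param series A [spectrum_series()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Character vector of paths written, invisibly.
#' @export
write_series <- function(series, dir, prefix = "spectrum_") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_along(series$members), function(i) {
    p <- file.path(dir, sprintf("%s%03d.txt", prefix, i))
    write_spectrum(series$members[[i]], p)
    p
  }, character(1))
  invisible(paths)
}
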