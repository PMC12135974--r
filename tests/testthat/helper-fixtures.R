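# shared fixture builders (all fixtures are generated in code)

gauss <- function(l, centre, sigma) exp(-((l - centre)^2) / (2 * sigma^2))

std_grid <- function() seq(300, 800, by = 1)

# the 12-point logarithmic time grid used for microsecond-to-second series
log_time_grid <- function() c(3e-6, 1e-5, 3e-5, 1e-4, 3e-4, 1e-3,
                              3e-3, 1e-2, 3e-2, 1e-1, 3e-1, 1)

write_tmp_lines <- function(lines, name = "fixture.txt") {
  path <- file.path(withr::local_tempdir(.local_envir = parent.frame()), name)
  writeLines(lines, path)
  path
}

# independent brute-force centre-value oracle for Savitzky-Golay windows
brute_savgol_centre <- function(y, i, window = 21, degree = 3) {
  k <- (window - 1) %/% 2
  win <- (i - k):(i + k)
  off <- win - i
  fit <- stats::lm(y[win] ~ poly(off, degree, raw = TRUE))
  unname(stats::predict(fit, newdata = data.frame(off = 0)))
}
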