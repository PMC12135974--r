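test_that("band traces reduce to columns, constants and additive integrals", {
  l <- std_grid()
  mk <- function(f, t) spectrum(l, f, label = t)
  y1 <- 0.4 * gauss(l, 450, 30); y2 <- 0.8 * gauss(l, 450, 30)
  ser <- spectrum_series(list(mk(y1, 1), mk(y2, 2)), axis = "time")

  # width-one band in mean mode equals that wavelength's values
  tr <- extract_time_trace(ser, c(450, 450), "mean")
  expect_equal(tr$values, c(y1[l == 450], y2[l == 450]))

  const <- spectrum_series(list(mk(rep(0.3, length(l)), 1),
                                mk(rep(0.3, length(l)), 2)), axis = "time")
  expect_equal(extract_time_trace(const, c(350, 750), "mean")$values, c(0.3, 0.3))

  # integrals over adjacent disjoint bands add up
  iAB <- extract_time_trace(ser, c(400, 500), "integral")$values
  iA <- extract_time_trace(ser, c(400, 450), "integral")$values
  iB <- extract_time_trace(ser, c(450, 500), "integral")$values
  expect_equal(iA + iB, iAB, tolerance = 1e-12)

  bad <- ser
  bad$members[[1]]$mask[band_idx <- which(l >= 700 & l <= 710)] <- TRUE
  expect_error(extract_time_trace(bad, c(700, 710), "mean"), "fully masked")
})

test_that("the M-state band trace rises then falls with the simulated maximum", {
  sc <- sim_scenario_br(seed = 2, od_sigma = 0, dent = FALSE)
  d <- difference_series(sc$series, sc$dark)
  tr <- extract_time_trace(d, c(395, 405), "mean")
  i_max <- which.max(tr$values)
  expect_gt(i_max, 1)
  expect_lt(i_max, length(tr$values))
  # occupancy law maximum: d/dt [hill(1e-4,2) * exp(-10 t)] = 0 near 1 ms
  m <- function(t) t^2 / (t^2 + 1e-8) * exp(-10 * t)
  t_dense <- 10^seq(-6, 0, by = 0.01)
  t_max_true <- t_dense[which.max(m(t_dense))]
  expect_equal(log10(tr$times[i_max]), log10(t_max_true), tolerance = 0.5)
})

test_that("noiseless exponential and Hill fits recover parameters to 0.01%", {
  t <- log_time_grid()
  y_exp <- 2 * exp(-1000 * t)
  f1 <- fit_kinetic(list(times = t, values = y_exp), "exp_decay")
  expect_lt(abs(f1$params$k - 1000) / 1000, 1e-4)
  expect_lt(abs(f1$params$y0 - 2), 1e-4)

  y_rise <- 1 - exp(-50 * t)
  f2 <- fit_kinetic(list(times = t, values = y_rise), "exp_rise")
  expect_lt(abs(f2$params$k - 50) / 50, 1e-4)

  y_hill <- 0.1 + 0.5 * t^2 / (t^2 + (1e-4)^2)
  f3 <- fit_kinetic(list(times = t, values = y_hill), "hill")
  expect_lt(abs(f3$params$K - 1e-4) / 1e-4, 1e-4)
  expect_lt(abs(f3$params$n - 2) / 2, 1e-4)
})

test_that("rates survive 1% multiplicative noise across 100 replicates", {
  t <- log_time_grid()
  y_exp <- 2 * exp(-1000 * t)
  y_hill <- 0.1 + 0.5 * t^2 / (t^2 + (1e-4)^2)
  set.seed(123)
  k_err <- K_err <- n_err <- numeric(100)
  for (r in 1:100) {
    fe <- fit_kinetic(list(times = t, values = y_exp * (1 + rnorm(12, 0, 0.01))),
                      "exp_decay")
    fh <- fit_kinetic(list(times = t, values = y_hill * (1 + rnorm(12, 0, 0.01))),
                      "hill")
    k_err[r] <- abs(fe$params$k - 1000) / 1000
    K_err[r] <- abs(fh$params$K - 1e-4) / 1e-4
    n_err[r] <- abs(fh$params$n - 2) / 2
  }
  expect_lt(median(k_err), 0.05)
  expect_lt(median(K_err), 0.10)
  expect_lt(median(n_err), 0.10)
})

test_that("fits are equivariant under time rescaling", {
  t <- log_time_grid()
  y_exp <- 1.5 * exp(-1000 * t) + 0.1
  y_hill <- 0.2 + 0.4 * t / (t + 1e-4)
  for (c in c(1e3, 1e-2)) {
    f <- fit_kinetic(list(times = c * t, values = y_exp), "exp_decay")
    expect_equal(f$params$k, 1000 / c, tolerance = 1e-3)
    h <- fit_kinetic(list(times = c * t, values = y_hill), "hill")
    expect_equal(h$params$K, c * 1e-4, tolerance = 1e-3)
    expect_equal(h$params$n, 1, tolerance = 1e-3)
  }
})

test_that("fit ranges and degenerate inputs are validated", {
  t <- log_time_grid()
  y <- 0.5 * exp(-100 * t)
  f <- fit_kinetic(list(times = t, values = y), "exp_decay",
                   fit_range = c(1e-5, 1e-1))
  expect_identical(f$n_points, sum(t >= 1e-5 & t <= 1e-1))
  expect_error(fit_kinetic(list(times = t[1:3], values = y[1:3]), "exp_decay"),
               "too few points")
  expect_error(fit_kinetic(list(times = t[1:4], values = y[1:4]), "hill"),
               "too few points")
})

test_that("uncertainties are returned from converged fits", {
  t <- log_time_grid()
  set.seed(9)
  y <- 2 * exp(-1000 * t) * (1 + rnorm(12, 0, 0.01))
  f <- fit_kinetic(list(times = t, values = y), "exp_decay")
  expect_true(is.finite(f$stderr$k))
  expect_gt(f$stderr$k, 0)
  expect_lt(f$stderr$k, 100)  # ~1% data noise => small rate uncertainty
})

test_that("serial-mode scaling equalizes the conserved band", {
  l <- std_grid()
  base <- 0.6 * gauss(l, 450, 25) + 0.2 * gauss(l, 560, 30)
  mk <- function(f, t) spectrum(l, f, label = t)

  f3 <- scale_series_pairwise(
    spectrum_series(list(mk(0.5 * base, 1), mk(base, 2), mk(2 * base, 3)),
                    axis = "time"), c(430, 470))
  expect_equal(f3$members[[1]]$values, f3$members[[2]]$values, tolerance = 1e-12)
  expect_equal(f3$members[[3]]$values, f3$members[[2]]$values, tolerance = 1e-12)

  # random lognormal thickness factors are removed to < 1% CV
  set.seed(31)
  members <- lapply(1:10, function(i) mk(base * rlnorm(1, 0, 0.3), i))
  scaled <- scale_series_pairwise(spectrum_series(members, axis = "time"),
                                  c(430, 470))
  maxima <- vapply(scaled$members, function(m)
    max(m$values[l >= 430 & l <= 470]), numeric(1))
  expect_lt(sd(maxima) / mean(maxima), 0.01)

  neg <- spectrum_series(list(mk(base, 1), mk(-base, 2)), axis = "time")
  expect_error(scale_series_pairwise(neg, c(430, 470)), "positive")
})
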