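test_that("constant-baseline correction zeroes the reference band and is idempotent", {
  grid <- std_grid()
  s <- spectrum(grid, rep(0.25, length(grid)))
  out <- constant_baseline_correct(s, c(650, 700))
  expect_true(all(abs(out$values) <= 1e-12))

  s2 <- spectrum(grid, 0.1 + 0.8 * gauss(grid, 430, 15))
  out2 <- constant_baseline_correct(s2, c(650, 700))
  idx <- which(grid >= 650 & grid <= 700)
  expect_lt(abs(mean(out2$values[idx])), 1e-12)
  out2b <- constant_baseline_correct(out2, c(650, 700))
  expect_equal(out2b$values, out2$values, tolerance = 1e-14)

  expect_error(constant_baseline_correct(s2, c(900, 950)), "band")
  masked <- s2
  masked$mask[idx] <- TRUE
  expect_error(constant_baseline_correct(masked, c(650, 700)), "masked")
})

test_that("Fresnel reflectivity and Cauchy dispersion behave as closed forms", {
  expect_equal(fresnel_reflectivity(1.4, 1.4), 0)
  expect_equal(fresnel_reflectivity(1.0, 1.5), 0.04)  # ((0.5)/(2.5))^2
  for (pair in list(c(1.2, 1.7), c(1.33, 1.5)))
    expect_equal(fresnel_reflectivity(pair[1], pair[2]),
                 fresnel_reflectivity(pair[2], pair[1]))
  expect_error(fresnel_reflectivity(-1, 1.5), "> 0")

  expect_equal(cauchy_index(1.4, 0, c(300, 500, 800)), rep(1.4, 3))
  expect_equal(cauchy_index(1.33, 3000, 500), 1.342)  # 1.33 + 3000/250000
  n <- cauchy_index(1.33, 3000, seq(300, 800, 50))
  expect_true(all(diff(n) < 0))
  expect_error(cauchy_index(1.33, 3000, -5), "> 0")
})

test_that("segment configuration rejects malformed segments", {
  expect_error(segment_config(list(c(400, 380))), "hi > lo")
  expect_error(segment_config(list(c(300, 400), c(350, 450))), "overlap")
  expect_error(segment_config(list(c(300, 350)), divergence = -1), "positive")
  expect_error(segment_config(list(c(1, 2), c(3, 4), c(5, 6), c(7, 8))), "1 to 3")
})

three_segments <- function() segment_config(list(c(310, 360), c(480, 505), c(650, 790)))

test_that("Rayleigh-only fits recover parameters to machine precision on clean data", {
  grid <- std_grid()
  e_true <- 2e9; c_true <- 0.05
  s <- spectrum(grid, e_true / grid^4 + c_true)
  fit <- fit_scattering_baseline(s, three_segments(), "rayleigh_only")
  expect_lt(abs(fit$params$e - e_true) / e_true, 1e-3)
  expect_lt(abs(fit$params$const - c_true), 1e-4)

  # lambda^-4 ratio identity when const = 0
  s0 <- spectrum(grid, e_true / grid^4)
  fit0 <- fit_scattering_baseline(s0, three_segments(), "rayleigh_only")
  ratio <- fit0$evaluate(400) / fit0$evaluate(800)
  expect_lt(abs(ratio - 16), 1e-6)
  # non-increasing in wavelength for e >= 0
  expect_true(all(diff(fit0$evaluate(seq(320, 780, 2))) <= 0))
})

test_that("power-law fits recover e, n and const", {
  grid <- std_grid()
  y <- 5e6 * grid^(-3) + 0.02
  s <- spectrum(grid, y)
  fit_fixed <- fit_scattering_baseline(s, three_segments(), "power_law", n = 3)
  expect_lt(abs(fit_fixed$params$e - 5e6) / 5e6, 1e-3)
  expect_lt(abs(fit_fixed$params$const - 0.02), 1e-4)
  fit_free <- fit_scattering_baseline(s, three_segments(), "power_law")
  expect_lt(abs(fit_free$params$n - 3) / 3, 1e-3)
  expect_lt(abs(fit_free$params$e - 5e6) / 5e6, 2e-2)
})

fresnel_truth <- function(grid, a = 1.33, b = 3000, c = 1.50, d = 4200, e = 2e9) {
  n1 <- a + b / grid^2
  n2 <- c + d / grid^2
  ((n1 - n2) / (n1 + n2))^2 + e / grid^4
}

test_that("the combined reflectivity + Rayleigh model recovers the true baseline under peaks", {
  grid <- std_grid()
  peaks <- 0.8 * gauss(grid, 430, 12) + 0.5 * gauss(grid, 560, 12)
  s <- spectrum(grid, fresnel_truth(grid) + peaks)
  cfg <- segment_config(list(c(310, 370), c(480, 505), c(660, 790)))
  fit <- fit_scattering_baseline(s, cfg, "fresnel_rayleigh")
  eval_grid <- seq(350, 750, by = 1)
  dev <- max(abs(fit$evaluate(eval_grid) - fresnel_truth(eval_grid)))
  expect_lt(dev, 0.01 * 0.8)  # within 1% of the largest peak amplitude
  expect_true(all(fit$evaluate(eval_grid) >= -1e-9))
  expect_length(fit$segment_rms, 3)
  expect_identical(nrow(fit$diagnostic), length(grid))
})

test_that("a huge divergence factor removes a segment's influence", {
  grid <- std_grid()
  y <- fresnel_truth(grid)
  y[grid >= 480 & grid <= 505] <- y[grid >= 480 & grid <= 505] + 0.5  # corrupt mid segment
  s <- spectrum(grid, y)
  cfg3 <- segment_config(list(c(310, 360), c(480, 505), c(650, 790)),
                         divergence = c(1, 1e6, 1))
  cfg2 <- segment_config(list(c(310, 360), c(650, 790)))
  f3 <- fit_scattering_baseline(s, cfg3, "rayleigh_only")
  f2 <- fit_scattering_baseline(s, cfg2, "rayleigh_only")
  expect_lt(max(abs(f3$evaluate(grid) - f2$evaluate(grid))), 1e-6)
})

test_that("the peak-fraction offset makes the fit run below the offset segment", {
  grid <- std_grid()
  # flat true baseline plus a peak that does not return to baseline on the blue side
  y <- 0.10 + 0.8 * gauss(grid, 430, 12)
  y[grid <= 370] <- y[grid <= 370] + 0.04  # residual absorption in the near-UV segment
  s <- spectrum(grid, y)
  cfg <- segment_config(list(c(310, 360), c(650, 790)),
                        offset_fraction = 0.05, offset_segment = 1)
  fit <- fit_scattering_baseline(s, cfg, "rayleigh_only",
                                 max_peak_band = c(400, 460))
  expect_equal(fit$offset, 0.05 * max(s$values), tolerance = 1e-12)
  # the fitted curve sits roughly offset below the near-UV points
  uv <- grid >= 310 & grid <= 360
  expect_equal(mean(s$values[uv] - fit$evaluate(grid[uv])), fit$offset,
               tolerance = 0.01)
  expect_error(fit_scattering_baseline(s, cfg, "rayleigh_only"), "max_peak_band")
})

test_that("adding a constant to the input is absorbed by the constant term", {
  grid <- std_grid()
  s <- spectrum(grid, fresnel_truth(grid) + 0.05)
  s_up <- spectrum(grid, s$values + 0.3)
  cfg <- three_segments()
  f1 <- fit_scattering_baseline(s, cfg, "rayleigh_only")
  f2 <- fit_scattering_baseline(s_up, cfg, "rayleigh_only")
  expect_equal(f2$params$const - f1$params$const, 0.3, tolerance = 1e-6)
  expect_equal(f2$params$e, f1$params$e, tolerance = 1e-6 * f1$params$e)
})

test_that("subtracting a fit brings the baseline to zero and preserves masks", {
  grid <- std_grid()
  s <- spectrum(grid, fresnel_truth(grid) + 0.05 + 0.8 * gauss(grid, 430, 12))
  s$mask[200:205] <- TRUE
  s$values[200:205] <- NaN
  cfg <- segment_config(list(c(310, 370), c(480, 505), c(660, 790)))
  fit <- fit_scattering_baseline(s, cfg, "fresnel_rayleigh")
  out <- subtract_baseline(s, fit)
  expect_identical(out$mask, s$mask)
  seg_idx <- which((grid >= 310 & grid <= 370) | (grid >= 660 & grid <= 790))
  expect_lt(abs(mean(out$values[setdiff(seg_idx, 200:205)])),
            max(fit$segment_rms) + 1e-6)
  # a re-fit of the corrected spectrum finds essentially no scattering left
  refit <- fit_scattering_baseline(out, cfg, "rayleigh_only")
  expect_lt(abs(refit$params$e), 0.01 * 2e9)
  expect_match(out$history[[length(out$history)]]$op, "subtract_baseline")
})

test_that("degenerate segment input is rejected", {
  grid <- std_grid()
  s <- spectrum(grid, 2e9 / grid^4)
  tiny <- segment_config(list(c(400, 400.4)))
  expect_error(fit_scattering_baseline(s, tiny, "rayleigh_only"), "at least 5|degenerate")
})

test_that("baseline diagnostics export as readable ASCII", {
  grid <- std_grid()
  s <- spectrum(grid, 2e9 / grid^4 + 0.05)
  fit <- fit_scattering_baseline(s, three_segments(), "rayleigh_only")
  path <- file.path(withr::local_tempdir(), "diag.txt")
  write_baseline_diagnostic(fit, path)
  lines <- readLines(path)
  expect_match(lines[2], "rayleigh_only")
  expect_identical(length(lines) - 4L, length(grid))
})
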