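test_that("two-column files parse and row order does not matter", {
  p1 <- write_tmp_lines(c("400 0.1", "401 0.2", "402 0.3"))
  s <- read_trace(p1)
  expect_s3_class(s, "spectrum")
  expect_equal(s$wavelengths, c(400, 401, 402))
  expect_equal(s$values, c(0.1, 0.2, 0.3))

  p2 <- write_tmp_lines(c("402 0.3", "401 0.2", "400 0.1"))
  s2 <- read_trace(p2)
  expect_equal(s2$wavelengths, s$wavelengths)
  expect_equal(s2$values, s$values)
})

test_that("dialect sniffing covers tabs, semicolons, commas and decimal commas", {
  cases <- list(
    list(lines = c("400\t1200", "401\t1300", "402\t1350"),
         wl = c(400, 401, 402), v = c(1200, 1300, 1350)),
    list(lines = c("400;1200", "401;1300", "402;1350"),
         wl = c(400, 401, 402), v = c(1200, 1300, 1350)),
    list(lines = c("400,1200", "401,1300", "402,1350"),
         wl = c(400, 401, 402), v = c(1200, 1300, 1350)),
    # decimal commas, semicolon-delimited
    list(lines = c("400,5;1200", "401,0;1300", "402,5;1350"),
         wl = c(400.5, 401, 402.5), v = c(1200, 1300, 1350)),
    # decimal commas, whitespace-delimited
    list(lines = c("400,5 0,1", "401,0 0,2", "402,5 0,3"),
         wl = c(400.5, 401, 402.5), v = c(0.1, 0.2, 0.3)))
  for (cs in cases) {
    p <- write_tmp_lines(cs$lines)
    tr <- read_trace(p)
    expect_equal(tr$wavelengths, cs$wl)
    expect_equal(if (inherits(tr, "raw_trace")) tr$counts else tr$values, cs$v)
  }
})

test_that("counts are sniffed into raw traces and headers are preserved", {
  p <- write_tmp_lines(c("Wavelength Counts", "integration 4 ms",
                         sprintf("%d %d", 400:404, c(1200L, 1250L, 1300L, 1280L, 1260L))))
  tr <- read_trace(p, role = "reference")
  expect_s3_class(tr, "raw_trace")
  expect_identical(tr$role, "reference")
  expect_match(tr$source_id, "integration 4 ms")
})

test_that("malformed files raise format errors", {
  expect_error(read_trace(file.path(tempdir(), "does-not-exist.txt")), "cannot read")
  p <- write_tmp_lines(c("only header", "400 1"))
  expect_error(read_trace(p), "fewer than 2 numeric rows")
  p2 <- write_tmp_lines(c("400 1", "400 2", "401 3"))
  expect_error(read_trace(p2), "duplicate wavelength 400")
})

test_that("write_spectrum round-trips values, masks and labels", {
  s <- spectrum(400:419, sin(seq(0, 1, length.out = 20)) + 0.123456789012,
                label = 0.3)
  s$mask[c(5, 11)] <- TRUE
  s$values[c(5, 11)] <- NaN
  s <- add_history(s, "compute_absorbance", list(n_masked = 2))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "out.txt")
  write_spectrum(s, path)
  expect_identical(sum(grepl("\\bnan\\b", readLines(path))), 2L)
  r <- read_trace(path, as = "absorbance")
  expect_equal(r$values[!r$mask], s$values[!s$mask], tolerance = 1e-9)
  expect_identical(which(r$mask), which(s$mask))
  expect_equal(r$label, 0.3)

  # empty history still writes a valid, re-readable file
  s2 <- spectrum(400:405, rep(0.5, 6))
  p2 <- file.path(dir, "plain.txt")
  write_spectrum(s2, p2)
  expect_equal(read_trace(p2, as = "absorbance")$values, s2$values)
})

test_that("filename labels parse with us/ms/s/Gy suffixes", {
  expect_equal(label_from_filename("t_000003us.txt"), 3e-6)
  expect_equal(label_from_filename("t_300ms.txt"), 0.3)
  expect_equal(label_from_filename("t_1s.txt"), 1)
  expect_equal(label_from_filename("dose_25Gy.txt"), 25)
  expect_equal(label_from_filename("crystal7_t_10us.txt"), 1e-5)
  expect_true(is.na(label_from_filename("nolabel.txt")))
})

test_that("read_series resamples to the common range and sorts by label", {
  dir <- withr::local_tempdir()
  stamps <- c("000003us", "00001s", "300ms", "10us", "30us", "000100us",
              "300us", "1ms", "3ms", "10ms", "30ms", "100ms")
  grid <- seq(300, 800, by = 1)
  for (st in stamps)
    write_spectrum(spectrum(grid, rep(0.5, length(grid))),
                   file.path(dir, sprintf("t_%s.txt", st)))
  ser <- read_series(file.path(dir, sprintf("t_%s.txt", stamps)))
  expect_length(ser$members, 12)
  expect_equal(ser$labels, log_time_grid())

  # grid = intersection of ranges, resampled onto the first member's grid
  p1 <- file.path(dir, "g_1s.txt"); p2 <- file.path(dir, "g_2s.txt")
  write_spectrum(spectrum(seq(300, 800), seq(300, 800) / 1000), p1)
  write_spectrum(spectrum(seq(350, 900), seq(350, 900) / 1000), p2)
  s2 <- read_series(c(p1, p2))
  expect_equal(range(s2$members[[1]]$wavelengths), c(350, 800))
  # linear data interpolates exactly
  expect_equal(s2$members[[2]]$values, s2$members[[1]]$values, tolerance = 1e-12)

  # output grid independent of input order
  s2r <- read_series(c(p2, p1))
  expect_equal(s2r$members[[1]]$wavelengths, s2$members[[1]]$wavelengths)

  # single file: index axis
  s1 <- read_series(p1, axis = "index")
  expect_length(s1$members, 1)

  # duplicate labels and disjoint ranges are errors
  p3 <- file.path(dir, "h_1s.txt")
  write_spectrum(spectrum(seq(300, 800), rep(1, 501)), p3)
  expect_error(read_series(c(p1, p3)), "duplicate labels")
  p4 <- file.path(dir, "far_2s.txt")
  write_spectrum(spectrum(seq(900, 1000), rep(1, 101)), p4)
  expect_error(read_series(c(p1, p4)), "disjoint")
})

test_that("manifest and explicit label rules work", {
  dir <- withr::local_tempdir()
  pa <- file.path(dir, "a.txt"); pb <- file.path(dir, "b.txt")
  write_spectrum(spectrum(400:500, rep(0.1, 101)), pa)
  write_spectrum(spectrum(400:500, rep(0.2, 101)), pb)
  man <- file.path(dir, "manifest.txt")
  writeLines(c("a.txt 0.5", "b.txt 0.25"), man)
  ser <- read_series(c(pa, pb), label_rule = "manifest", manifest = man)
  expect_equal(ser$labels, c(0.25, 0.5))
  expect_equal(ser$members[[1]]$values[1], 0.2)  # sorted by label
  ser2 <- read_series(c(pa, pb), label_rule = "explicit", labels = c(2, 1))
  expect_equal(ser2$labels, c(1, 2))
})

test_that("series construction validates its invariants", {
  a <- spectrum(400:500, rep(1, 101))
  b <- spectrum(401:501, rep(1, 101))
  expect_error(spectrum_series(list(a, b), axis = "index"), "identical wavelength grid")
  expect_error(spectrum_series(list(a, a), axis = "time", labels = c(2, 1)),
               "strictly increasing")
})
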