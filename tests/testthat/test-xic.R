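gauss_peaks <- function(mz, rt_apex, amplitude, sigma) {
  data.frame(mz = mz, rt_apex = rt_apex, amplitude = amplitude, sigma = sigma)
}

test_that("ms1_map validates ordering and intensities", {
  expect_error(ms1_map(c(2, 1), list(cbind(1, 1), cbind(1, 1))), "increasing")
  expect_error(ms1_map(1, list(cbind(100, -1))), "negative")
  # unsorted m/z within a scan gets sorted
  m <- ms1_map(1, list(cbind(c(200, 100), c(1, 2))))
  expect_equal(m$peaks[[1]][, 1], c(100, 200))
})

test_that("mzML write/read round-trips MS1 scans through mzR", {
  map <- simulate_ms1_map(gauss_peaks(500.25, 300, 1e6, 10),
                          rt_range = c(250, 350), sampling_interval = 2)
  f <- withr::local_tempfile(fileext = ".mzML")
  write_ms1_scans(map, f)
  back <- read_ms1_scans(f)
  expect_equal(back$rt, map$rt, tolerance = 1e-6)
  expect_equal(length(back$peaks), length(map$peaks))
  expect_equal(back$peaks[[26]][, "intensity"], map$peaks[[26]][, "intensity"],
               tolerance = 1e-6, ignore_attr = TRUE)
  # minutes unit conversion on read
  mins <- read_ms1_scans(f, rt_unit = "minutes")
  expect_equal(mins$rt, map$rt * 60, tolerance = 1e-6)
})

test_that("XIC extraction traces matching ions and zeroes the rest", {
  # one ion exactly at the query m/z in every scan
  ints <- c(1, 5, 9, 5, 1)
  map <- ms1_map(1:5, lapply(ints, function(i) cbind(400.2, i)))
  ch <- extract_xic(map, 400.2, ppm_tol = 10, rt_center = 3, rt_window = 10)
  expect_equal(ch$intensity, ints)
  expect_equal(ch$rt, 1:5)

  # all ions outside tolerance -> zeros (10 ppm of 400.2 is ~0.004 Th)
  ch2 <- extract_xic(map, 400.3, ppm_tol = 10, rt_center = 3, rt_window = 10)
  expect_equal(ch2$intensity, rep(0, 5))

  # two ions inside tolerance are summed
  map3 <- ms1_map(1, list(cbind(c(400.2, 400.2005), c(2, 3))))
  ch3 <- extract_xic(map3, 400.2, ppm_tol = 10, rt_center = 1, rt_window = 4)
  expect_equal(ch3$intensity, 5)

  # empty RT window is an empty chromatogram, not an error
  ch4 <- extract_xic(map, 400.2, ppm_tol = 10, rt_center = 100, rt_window = 10)
  expect_length(ch4$rt, 0)
  expect_equal(integrate_peak_area(ch4, 100)$area, 0)
})

test_that("peak integration recovers the closed-form Gaussian area within 1%", {
  set.seed(12)
  for (i in 1:20) {
    A <- runif(1, 1e3, 1e7)
    sig <- runif(1, 4, 25)
    apex <- runif(1, 250, 350)
    map <- simulate_ms1_map(gauss_peaks(600.1, apex, A, sig),
                            rt_range = c(0, 600), sampling_interval = 0.5)
    ch <- extract_xic(map, 600.1, rt_center = apex, rt_window = 300)
    res <- integrate_peak_area(ch, apex)
    truth <- A * sig * sqrt(2 * pi)
    expect_lt(abs(res$area - truth) / truth, 0.01)
    expect_true(res$left_rt <= res$apex_rt && res$apex_rt <= res$right_rt)
  }
})

test_that("degenerate chromatograms integrate to zero", {
  z <- structure(list(rt = 1:10, intensity = rep(0, 10)),
                 class = "chromatogram")
  expect_equal(integrate_peak_area(z, 5)$area, 0)
  one <- structure(list(rt = 5, intensity = 100), class = "chromatogram")
  r1 <- integrate_peak_area(one, 5)
  expect_equal(r1$area, 0)
  expect_equal(r1$n_points, 1L)
})

test_that("area is invariant under RT translation and linear in intensity", {
  A <- 5e4; sig <- 8
  base <- simulate_ms1_map(gauss_peaks(500, 300, A, sig),
                           rt_range = c(200, 400), sampling_interval = 1)
  shifted <- simulate_ms1_map(gauss_peaks(500, 1300, A, sig),
                              rt_range = c(1200, 1400), sampling_interval = 1)
  a0 <- integrate_peak_area(extract_xic(base, 500, rt_center = 300), 300)$area
  a1 <- integrate_peak_area(extract_xic(shifted, 500, rt_center = 1300), 1300)$area
  expect_equal(a0, a1, tolerance = 1e-9)

  double <- simulate_ms1_map(gauss_peaks(500, 300, 2 * A, sig),
                             rt_range = c(200, 400), sampling_interval = 1)
  a2 <- integrate_peak_area(extract_xic(double, 500, rt_center = 300), 300)$area
  expect_equal(a2, 2 * a0, tolerance = 1e-9)
})

test_that("halving the sampling interval changes the area by < 0.5%", {
  A <- 1e5; sig <- 10
  coarse <- simulate_ms1_map(gauss_peaks(500, 300, A, sig),
                             rt_range = c(200, 400), sampling_interval = 2)
  fine <- simulate_ms1_map(gauss_peaks(500, 300, A, sig),
                           rt_range = c(200, 400), sampling_interval = 1)
  ac <- integrate_peak_area(extract_xic(coarse, 500, rt_center = 300), 300)$area
  af <- integrate_peak_area(extract_xic(fine, 500, rt_center = 300), 300)$area
  expect_lt(abs(ac - af) / af, 0.005)
})

test_that("per-PSM XIC features recover areas and handle missing precursors", {
  peaks <- gauss_peaks(c(450.5, 700.8), c(150, 400), c(2e5, 8e5), c(6, 12))
  map <- simulate_ms1_map(peaks, rt_range = c(0, 600), sampling_interval = 0.5)
  feats <- cbind(score = c(1, 2, 3),
                 PrecursorMz = c(450.5, 700.8, 900.0),
                 RetentionTime = c(150, 400, 500))
  psms <- psm_table(c("a", "b", "c"), c("target", "target", "decoy"),
                    1:3, c("PEPK", "PEPR", "DECK"),
                    list("p1", "p2", "decoy_p3"), feats)
  x <- assign_xic_features(psms, map)
  truths <- peaks$amplitude * peaks$sigma * sqrt(2 * pi)
  expect_lt(abs(x[["a"]] - truths[1]) / truths[1], 0.01)
  expect_lt(abs(x[["b"]] - truths[2]) / truths[2], 0.01)
  expect_equal(unname(x[["c"]]), 0)  # precursor absent from the map

  # permuting the PSM order permutes the values with it
  x2 <- assign_xic_features(psms[c(3, 1, 2), ], map)
  expect_equal(x2[names(x)], x)
})

test_that("simulated two peaks 100 ppm apart resolve independently at 10 ppm", {
  mz0 <- 600
  peaks <- gauss_peaks(c(mz0, mz0 * (1 + 100e-6)), c(300, 300), c(1e5, 3e5),
                       c(8, 8))
  map <- simulate_ms1_map(peaks, rt_range = c(200, 400), sampling_interval = 0.5)
  a1 <- integrate_peak_area(extract_xic(map, peaks$mz[1], rt_center = 300), 300)$area
  a2 <- integrate_peak_area(extract_xic(map, peaks$mz[2], rt_center = 300), 300)$area
  truths <- peaks$amplitude * peaks$sigma * sqrt(2 * pi)
  expect_lt(abs(a1 - truths[1]) / truths[1], 0.01)
  expect_lt(abs(a2 - truths[2]) / truths[2], 0.01)
})
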