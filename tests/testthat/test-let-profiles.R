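test_that("resampling is exact on linear profiles and refuses extrapolation", {
  p <- dose_profile(c(0, 10, 20), c(0, 5, 10), "depth", "chamber")
  same <- resample(p, c(0, 10, 20))
  expect_equal(same$value, p$value)
  mid <- resample(p, c(2.5, 7.5, 13))
  expect_equal(mid$value, c(1.25, 3.75, 6.5))
  expect_error(resample(p, c(-1, 5)), "span")
  expect_error(resample(p, c(5, 25)), "span")
})

test_that("relative dose difference is pointwise and flags unreliable tails", {
  z <- 0:10
  c_ <- dose_profile(z, c(rep(10, 8), 5, 0.05, 0), "depth", "chamber")
  f_same <- dose_profile(z, c(rep(10, 8), 5, 0.05, 0), "depth", "film-red")
  d0 <- relative_dose_difference(f_same, c_)
  expect_equal(d0$diff_pct[1:9], rep(0, 9))
  expect_true(is.na(d0$diff_pct[11]))          # chamber zero: no ratio
  expect_false(d0$reliable[10])                # below 1% of maximum
  f_low <- dose_profile(z, 0.8 * c_$value, "depth", "film-red")
  d <- relative_dose_difference(f_low, c_)
  expect_equal(d$diff_pct[1:10], rep(-20, 10), tolerance = 1e-9)
  # antisymmetry identity between the two orientations of the comparison
  dd_fc <- relative_dose_difference(f_low, c_)$diff_pct[1]
  dd_cf <- relative_dose_difference(c_, f_low)$diff_pct[1]
  expect_equal(dd_fc, -dd_cf / (1 + dd_cf / 100), tolerance = 1e-9)
})

test_that("central-axis normalization anchors 100%, is idempotent and scale-free", {
  x <- seq(-60, 60, by = 1)
  v <- 80 * exp(-abs(x + 3) / 40)   # deliberately asymmetric
  p <- dose_profile(x, v, "lateral", "film-red")
  n1 <- normalize_central_axis(p)
  expect_equal(n1$value[x == 0], 100)
  n2 <- normalize_central_axis(n1)
  expect_equal(n2$value, n1$value, tolerance = 1e-12)
  n7 <- normalize_central_axis(dose_profile(x, 7 * v, "lateral", "film-red"))
  expect_equal(n7$value, n1$value, tolerance = 1e-12)
  # asymmetry is preserved
  expect_false(isTRUE(all.equal(n1$value, rev(n1$value))))
  expect_error(normalize_central_axis(dose_profile(1:10, 1:10, "lateral", "chamber")),
               "span")
})

test_that("level crossings interpolate linearly outward from the center", {
  p <- dose_profile(c(0, 10, 20), c(100, 50, 0), "lateral", "chamber")
  cr <- level_crossings(p, levels = c(50, 25))
  expect_equal(unname(cr["L50"]), 10)
  expect_equal(unname(cr["L25"]), 15)
  expect_equal(unname(level_crossings(p, levels = 100)[1]), 0)
  expect_true(is.na(level_crossings(dose_profile(0:5, rep(80, 6), "lateral",
                                                 "chamber"), 50)[1]))
  # crossings on the synthetic penumbra land at the construction's edges
  beam <- beam_truth()
  lat <- simulate_lateral_profiles(beam)
  cr50 <- level_crossings(lat$chamber, 50)
  expect_equal(unname(cr50), beam$field_half_width, tolerance = 1e-3)
  neg <- level_crossings(lat$chamber, 50, side = "negative")
  expect_equal(unname(neg), -beam$field_half_width, tolerance = 1e-3)
  # evaluating the profile back at the crossings reproduces the levels
  lv <- c(50, 20, 5)
  pos <- level_crossings(lat$chamber, lv)
  expect_equal(resample(lat$chamber, sort(pos))$value, lv, tolerance = 0.05)
})

test_that("deviation tables subtract film and chamber percentages exactly", {
  # piecewise-linear shoulders through the published comparison points
  chamber <- dose_profile(c(-60, 0, 51, 55, 58, 60),
                          c(100, 100, 52.6, 18.7, 6.0, 4),
                          "lateral", "chamber")
  film <- dose_profile(c(-60, 0, 51, 55, 58, 60),
                       c(100, 100, 51.7, 16.1, 4.8, 3),
                       "lateral", "film-red")
  tb <- lateral_deviation_table(film, chamber, c(51, 55, 58))
  expect_equal(tb$deviation_pp, c(51.7 - 52.6, 16.1 - 18.7, 4.8 - 6.0),
               tolerance = 1e-9)
  expect_equal(tb$deviation_pp[1], -0.9, tolerance = 1e-9)
  # the 150 mm depth point with a film over-response: +2.9 pp
  ch2 <- dose_profile(c(-60, 0, 64, 70), c(100, 100, 5.6, 3), "lateral", "chamber")
  f2 <- dose_profile(c(-60, 0, 64, 70), c(100, 100, 8.5, 5), "lateral", "film-red")
  tb2 <- lateral_deviation_table(f2, ch2, 64)
  expect_equal(tb2$deviation_pp, 2.9, tolerance = 1e-9)
  # equality everywhere gives all-zero deviations
  tb0 <- lateral_deviation_table(chamber, chamber, c(51, 55, 58))
  expect_equal(tb0$deviation_pp, rep(0, 3))
  # unnormalized inputs are refused
  bad <- dose_profile(c(-60, 0, 60), c(90, 90, 10), "lateral", "film-red")
  expect_error(lateral_deviation_table(bad, chamber, 51), "normalized")
})

test_that("peak under-response recovers the constructed quench magnitude", {
  beam <- beam_truth(quench_max = 0.18)
  p <- simulate_depth_profiles(beam)
  expect_equal(peak_under_response(p$film_response, p$chamber, window = 1),
               -18, tolerance = 0.5)
  beam0 <- beam_truth(quench_max = 0)
  p0 <- simulate_depth_profiles(beam0)
  expect_equal(peak_under_response(p0$film_response, p0$chamber), 0)
  # a window wider than the quench ramp averages to a smaller magnitude
  wide <- peak_under_response(p$film_response, p$chamber, window = 12)
  expect_lt(abs(wide), 18)
  # noiseless end-to-end: extracted difference equals the generator quench
  dd <- relative_dose_difference(p$film_response, p$chamber)
  q <- 0.18 * pmin(pmax((dd$position_mm - (beam$peak_depth - 15)) / 15, 0), 1)
  ok <- dd$reliable
  expect_lt(max(abs(dd$diff_pct[ok] - (-100 * q[ok]))), 0.5)
})

test_that("profiles survive a CSV round trip with metadata", {
  p <- dose_profile(seq(0, 30, by = 5), c(1, 2, 4, 8, 4, 2, 1) / 8,
                    "depth", "film-green")
  path <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(p, path)
  back <- read_profile_csv(path)
  expect_equal(back$position_mm, p$position_mm)
  expect_equal(back$value, p$value)
  expect_identical(attr(back, "geometry"), "depth")
  expect_identical(attr(back, "source"), "film-green")
})
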