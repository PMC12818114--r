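make_group <- function(label, dose, netods_by_channel) {
  rows <- do.call(rbind, lapply(names(netods_by_channel), function(ch)
    data.frame(channel = ch, netod = netods_by_channel[[ch]])))
  measurement_group(label, dose, rows)
}

test_that("percent difference is symmetric and matches worked values", {
  # the day-1 / day-2 red-channel pair at 10 Gy
  expect_equal(percent_difference(0.4426, 0.4403), 0.521057, tolerance = 1e-4)
  expect_lt(percent_difference(0.4426, 0.4403), 1)
  expect_equal(percent_difference(0.37, 0.37), 0)
  expect_equal(percent_difference(2, 1), 100 * 1 / 1.5, tolerance = 1e-12)
  expect_equal(percent_difference(2, 1), percent_difference(1, 2))
  expect_error(percent_difference(0, 1), "positive")
})

test_that("reproducibility compares session means per channel at matched dose", {
  g1 <- make_group("day1", 10, list(red = c(0.44, 0.45), green = 0.30, blue = 0.10))
  g2 <- make_group("day2", 10, list(red = c(0.44, 0.45), green = 0.30, blue = 0.10))
  expect_equal(unname(reproducibility(g1, g2)), rep(0, 3))
  g3 <- make_group("day2", 10, list(red = 0.4403, green = 0.30, blue = 0.10))
  g4 <- make_group("day1", 10, list(red = 0.4426, green = 0.30, blue = 0.10))
  expect_equal(reproducibility(g4, g3)[["red"]], 0.521057, tolerance = 1e-4)
  g5 <- make_group("day2", 5, list(red = 0.3, green = 0.2, blue = 0.1))
  expect_error(reproducibility(g1, g5), "different doses")
})

test_that("energy dependence is the max deviation from the grand mean", {
  mk <- function(lab, r) make_group(lab, 5, list(red = r, green = r / 2, blue = r / 4))
  expect_equal(unname(energy_dependence(list(mk("70", 0.3), mk("150", 0.3),
                                             mk("225", 0.3)))), rep(0, 3))
  # the three per-energy red means 0.30 / 0.32 / 0.33: grand mean 0.31667,
  # largest deviation 0.01667 (the 0.30 group) -> 5.263%
  e <- energy_dependence(list(mk("70", 0.30), mk("150", 0.32), mk("225", 0.33)))
  expect_equal(e[["red"]], 100 * (0.31666667 - 0.30) / 0.31666667, tolerance = 1e-6)
  expect_equal(e[["red"]], 5.263158, tolerance = 1e-5)
  # two-group closed form: {x, x(1+eps)} -> 100*eps/(2+eps)
  eps <- 0.04
  e2 <- energy_dependence(list(mk("a", 0.3), mk("b", 0.3 * (1 + eps))))
  expect_equal(e2[["red"]], 100 * eps / (2 + eps), tolerance = 1e-9)
  expect_error(energy_dependence(list(mk("a", 0.3))), ">= 2")
})

test_that("sensitivity deviation is signed and normalized by the prediction", {
  cal <- simulate_calibration_dataset(preset_truth("B1"),
                                      noise = noise_spec(fraction = 0, seed = 5))
  model <- suppressWarnings(fit_calibration(cal, batch = "B1"))
  pred <- vapply(c("red", "green", "blue"),
                 function(ch) eval_forward(model, 5, channel = ch), numeric(1))
  tri <- data.frame(channel = c("red", "green", "blue"), netod = pred)
  expect_equal(unname(sensitivity_deviation(tri, model, 5)), rep(0, 3),
               tolerance = 1e-9)
  tri_up <- transform(tri, netod = netod * 1.015)
  expect_equal(unname(sensitivity_deviation(tri_up, model, 5)), rep(1.5, 3),
               tolerance = 1e-9)
  expect_error(sensitivity_deviation(tri, model, 0), "> 0")
})

test_that("dose resolvability applies the k*sqrt(2)*sigma separation rule", {
  truth <- preset_truth("B1")
  expect_false(resolvable(5, 5, truth, 1e-4)[["red"]])
  expect_true(all(resolvable(5, 5.25, truth, 0)))
  # +5% at 0.5 Gy against sigma = 4e-4 on the red channel
  dnet <- rational_oracle(0.525, 0.0740, 0.0842, 0.9684) -
    rational_oracle(0.5, 0.0740, 0.0842, 0.9684)
  expect_gt(dnet, 2 * sqrt(2) * 4e-4)   # 1.7e-3 vs 1.13e-3
  expect_true(resolvable(0.5, 0.525, truth, 4e-4)[["red"]])
  # monotone in separation: a wider dose pair stays resolvable at equal sigma
  expect_true(resolvable(0.5, 0.55, truth, 4e-4)[["red"]])
  expect_error(resolvable(1, 2, truth, -1e-3), ">= 0")
})

test_that("batch variation reproduces the model-based B1-vs-B2 gap at 10 Gy", {
  n1 <- rational_oracle(10, 0.0740, 0.0842, 0.9684)
  n2 <- rational_oracle(10, 0.1084, 0.2339, 0.7978)
  expected <- 100 * abs(n1 - n2) / ((n1 + n2) / 2)   # 5.66%
  gA <- make_group("B1", 10, list(red = n1, green = 0.3, blue = 0.1))
  gB <- make_group("B2", 10, list(red = n2, green = 0.3, blue = 0.1))
  expect_equal(batch_variation(gA, gB)[["red"]], expected, tolerance = 1e-9)
  expect_equal(expected, 5.66, tolerance = 1e-2)
  expect_equal(batch_variation(gA, gA)[["red"]], 0)
  # worked example: means 0.40 vs 0.45 differ by 11.76%
  gx <- make_group("x", 10, list(red = 0.40, green = 0.3, blue = 0.1))
  gy <- make_group("y", 10, list(red = 0.45, green = 0.3, blue = 0.1))
  expect_equal(batch_variation(gx, gy)[["red"]], 100 * 0.05 / 0.425,
               tolerance = 1e-9)
})

test_that("noise-to-signal averages sigma/netod and orders channels red < green < blue", {
  ds0 <- data.frame(dose_gy = c(5, 5, 5), channel = c("red", "green", "blue"),
                    netod = c(0.3, 0.2, 0.1), sigma = 0)
  expect_equal(unname(noise_to_signal(ds0)), rep(0, 3))
  ds1 <- data.frame(dose_gy = 5, channel = "red", netod = 0.4, sigma = 0.01)
  expect_equal(noise_to_signal(ds1)[["red"]], 2.5)
  # default synthetic noise gives the expected channel quality ordering
  ds <- simulate_calibration_dataset(preset_truth("B1"),
                                     noise = noise_spec(seed = 8),
                                     replicates = 2)
  nsr <- noise_to_signal(ds)
  expect_lt(nsr[["red"]], nsr[["green"]])
  expect_lt(nsr[["green"]], nsr[["blue"]])
  ds_bad <- data.frame(dose_gy = c(1, 2), channel = "red",
                       netod = c(-0.01, 0.1), sigma = 0.001)
  expect_warning(noise_to_signal(ds_bad), "excluded")
})

test_that("statistics are invariant under a common netOD scale factor", {
  set.seed(31)
  vals <- list(red = runif(5, 0.3, 0.5), green = runif(5, 0.2, 0.3),
               blue = runif(5, 0.05, 0.1))
  vals2 <- lapply(vals, function(v) v * runif(length(v), 0.95, 1.05))
  for (c_ in c(0.5, 3)) {
    g1 <- make_group("a", 5, vals)
    g2 <- make_group("b", 5, vals2)
    g1s <- make_group("a", 5, lapply(vals, `*`, c_))
    g2s <- make_group("b", 5, lapply(vals2, `*`, c_))
    expect_equal(reproducibility(g1s, g2s), reproducibility(g1, g2),
                 tolerance = 1e-12)
    expect_equal(energy_dependence(list(g1s, g2s)),
                 energy_dependence(list(g1, g2)), tolerance = 1e-12)
  }
})

test_that("group-mean noise shrinks the energy statistic like 1/sqrt(films)", {
  truth_netod <- 0.3
  sim_stat <- function(films, seed) {
    set.seed(seed)
    groups <- lapply(1:3, function(g) {
      make_group(paste(g), 5, list(red = truth_netod * (1 + 0.01 * rnorm(films)),
                                   green = 0.2, blue = 0.1))
    })
    energy_dependence(groups)[["red"]]
  }
  s1 <- vapply(1:60, function(i) sim_stat(2, i), numeric(1))
  s2 <- vapply(1:60, function(i) sim_stat(32, 1000 + i), numeric(1))
  ratio <- mean(s1) / mean(s2)
  expect_gt(ratio, 2)   # sqrt(16) = 4 expected; allow generous slack
  expect_lt(ratio, 8)
})
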