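test_that("TIFF round trip is lossless and rejects non-conforming input", {
  set.seed(11)
  arr <- array(sample(0:65535, 16 * 16 * 3, replace = TRUE), dim = c(16, 16, 3))
  frame <- scan_frame(arr, dpi = 300, acquired_at = 48,
                      metadata = list(piece = "p1"))
  path <- withr::local_tempfile(fileext = ".tif")
  save_scan(frame, path)
  back <- load_scan(path)
  expect_identical(back$data, frame$data + 0)  # numeric comparison
  expect_equal(back$dpi, 300)
  expect_equal(back$acquired_at, 48)
  expect_identical(back$metadata$piece, "p1")
  # 8-bit input is refused with a format message
  path8 <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(array(0.5, dim = c(8, 8, 3)), path8, bits.per.sample = 8L)
  expect_error(load_scan(path8), "16 bits")
  expect_error(load_scan(withr::local_tempfile(fileext = ".tif")), "not found")
})

test_that("ROI statistics match constant and checkerboard constructions", {
  f <- uniform_frame(40000)
  s <- roi_stats(f, roi(0, 0, 16, 16))
  expect_equal(s$mean, rep(40000, 3))
  expect_equal(s$sd, rep(0, 3))
  expect_equal(s$n, rep(256L, 3))
  checker <- array(rep(c(30000, 50000), length.out = 16 * 16 * 3),
                   dim = c(16, 16, 3))
  expect_equal(roi_stats(scan_frame(checker), roi(0, 0, 16, 16))$mean,
               rep(40000, 3))
  expect_error(roi(0, 0, 2, 2), ">= 4")
  expect_error(roi_stats(f, roi(10, 10, 8, 8)), "exceeds")
  # the central-ROI convention covers half of each dimension, centered
  cr <- central_roi(uniform_frame(1, shape = c(32L, 64L)))
  expect_equal(c(cr$width, cr$height), c(32L, 16L))
  expect_equal(c(cr$x0, cr$y0), c(16L, 8L))
})

test_that("netOD and its uncertainty follow the log-ratio propagation", {
  st <- function(mean, sd = 0, n = 256) list(mean = mean, sd = sd, n = n)
  # exact decade and identity, both noise-free
  expect_equal(compute_netod(st(40000), st(4000))$netod, 1)
  expect_equal(compute_netod(st(40000), st(4000))$sigma, 0)
  expect_equal(compute_netod(st(30000), st(30000))$netod, 0)
  # 1% relative error on both signals (as pixel sd): (1/ln 10)*sqrt(2e-4)
  pre <- st(40000, sd = 400, n = 256)
  post <- st(4000, sd = 40, n = 256)
  r <- compute_netod(pre, post, pixel_sd = TRUE)
  expect_equal(r$sigma, sqrt(2 * 1e-4) / log(10), tolerance = 1e-12)
  # the scaled convention multiplies by netOD
  pre5 <- st(40000, sd = 400, n = 256)
  post5 <- st(40000 / 10^0.5, sd = 40000 / 10^0.5 / 100, n = 256)
  r5 <- compute_netod(pre5, post5, sigma_form = "scaled", pixel_sd = TRUE)
  expect_equal(r5$sigma, 0.5 * sqrt(2 * 1e-4) / log(10), tolerance = 1e-12)
  # default sigma uses the standard error of the ROI mean
  rs <- compute_netod(pre, post)
  expect_equal(rs$sigma, sqrt(2 * 1e-4 / 256) / log(10), tolerance = 1e-12)
  expect_error(compute_netod(st(100), st(1000)), "lighter")
})

test_that("netOD is additive across intermediate frames (log-ratio oracle)", {
  st <- function(mean) list(mean = mean, sd = 0, n = 256)
  set.seed(21)
  for (i in 1:20) {
    m <- sort(runif(3, 1000, 60000), decreasing = TRUE)
    ac <- compute_netod(st(m[1]), st(m[3]))$netod
    ab <- compute_netod(st(m[1]), st(m[2]))$netod
    bc <- compute_netod(st(m[2]), st(m[3]))$netod
    expect_equal(ac, ab + bc, tolerance = 1e-12)
  }
})

test_that("sigma is invariant under common scaling of both frames", {
  st <- function(mean, sd) list(mean = mean, sd = sd, n = 64)
  base <- compute_netod(st(40000, 200), st(20000, 150))
  for (c_ in c(0.3, 2.5)) {
    scaled <- compute_netod(st(40000 * c_, 200 * c_), st(20000 * c_, 150 * c_))
    expect_equal(scaled$sigma, base$sigma, tolerance = 1e-12)
    expect_equal(scaled$netod, base$netod, tolerance = 1e-12)
  }
})

test_that("netOD maps compute pixelwise log-ratios with masking", {
  pre <- uniform_frame(40000)
  post <- uniform_frame(4000)
  m <- netod_map(pre, post)
  expect_true(all(m == 1))
  m0 <- netod_map(pre, pre)
  expect_true(all(m0 == 0))
  bad <- post
  bad$data[3, 5, 2] <- 0
  mb <- netod_map(pre, bad)
  expect_true(is.na(mb[3, 5, 2]))
  expect_equal(sum(is.na(mb)), 1L)
  expect_error(netod_map(pre, uniform_frame(4000, shape = c(8L, 8L))),
               "dimensions")
})

test_that("ROI-mean netOD and mean-of-map netOD agree within the Jensen gap", {
  truth <- preset_truth("B1")
  ns <- noise_spec(fraction = 0.02, seed = 13)
  pair <- simulate_scan_pair(5, truth, ns, shape = c(64L, 64L))
  r <- central_roi(pair$pre)
  tri <- netod_triplet(pair$pre, pair$post, r, pixel_sd = TRUE)
  m <- netod_map(pair$pre, pair$post)
  idx <- list(rows = (r$y0 + 1):(r$y0 + r$height), cols = (r$x0 + 1):(r$x0 + r$width))
  for (k in 1:3) {
    map_mean <- mean(m[idx$rows, idx$cols, k])
    gap <- abs(map_mean - tri$netod[k])
    # second-order (Jensen) bound on E[log X] - log E[X] with sigma = pixel rel sd
    bound <- tri$sigma[k]^2 * log(10) / 2 + 1e-6
    expect_lt(gap, bound)
  }
})

test_that("profiles extract central bands with mm positions from dpi", {
  expect_equal(25.4 / 300, 0.08466667, tolerance = 1e-7)  # pixel pitch at 300 dpi
  flat <- array(0.3, dim = c(16, 40, 3))
  attr(flat, "dpi") <- 300
  p <- extract_profile(flat, "red", axis = "depth", band_halfwidth = 2)
  expect_equal(p$value, rep(0.3, 40))
  expect_equal(diff(p$position_mm), rep(25.4 / 300, 39), tolerance = 1e-12)
  # a linear gradient along x survives extraction with the same slope per mm
  grad <- array(rep(seq(0, 1, length.out = 40), each = 16), dim = c(16, 40, 3))
  attr(grad, "dpi") <- 300
  pg <- extract_profile(grad, "green", axis = "depth", band_halfwidth = 3)
  slopes <- diff(pg$value) / diff(pg$position_mm)
  expect_equal(slopes, rep(slopes[1], 39), tolerance = 1e-9)
  expect_error(extract_profile(flat, "red", band_halfwidth = 20), "band")
})
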