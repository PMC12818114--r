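#' Simulate a pre/post scan pair for one film piece
#'
#' Generates two [scan_frame()]s emulating a flatbed transmission scan of
#' the same film piece before and after a uniform dose.  The unexposed
#' signal is `I0_mean` counts in every channel; after a dose `D` the signal
#' attenuates by the batch's dose response, `I = I0 * 10^(-netOD(D))`.
#' Independent multiplicative Gaussian noise of the per-channel fraction in
#' `noise` is applied per pixel, then values are clipped to the 16-bit range
#' `[0, 65535]`.  If more than 1 % of pixels clip, `metadata$clipped` is set
#' and a warning is raised.  Simulation is bit-reproducible for a fixed
#' `noise$seed`.
#'
#' @param dose Delivered dose in Gy, >= 0.
#' @param truth A [calibration_truth()] (e.g. [preset_truth()]).
#' @param noise A [noise_spec()].
#' @param shape Frame extent `c(height, width)` in pixels, each >= 8.
#' @param dpi Scan resolution recorded in the frames.
#' @return A list with elements `pre` and `post`, both [scan_frame()]s.
#' @export
simulate_scan_pair <- function(dose, truth, noise = noise_spec(),
                               shape = c(32L, 32L), dpi = 300) {
  stopifnot(inherits(truth, "calibration_truth"), inherits(noise, "noise_spec"))
  if (dose < 0) stop_pf("dose must be >= 0")
  shape <- as.integer(rep_len(shape, 2L))
  if (any(shape < 8L)) stop_pf("frame shape must be at least 8 x 8 px")
  set.seed(noise$seed)
  make <- function(level_by_channel) {
    arr <- array(0, dim = c(shape, 3L))
    clipped <- 0L
    for (k in seq_along(CHANNELS)) {
      mu <- level_by_channel[k]
      px <- matrix(mu, shape[1], shape[2])
      f <- noise$fraction[[CHANNELS[k]]]
      if (f > 0) px <- px * (1 + f * matrix(stats::rnorm(prod(shape)), shape[1], shape[2]))
      clipped <- clipped + sum(px < 0 | px > 65535)
      arr[, , k] <- pmin(pmax(px, 0), 65535)
    }
    meta <- list(dose_gy = dose, batch = truth$batch, seed = noise$seed)
    if (clipped > 0.01 * prod(shape) * 3) {
      meta$clipped <- TRUE
      warning(sprintf("%d pixels clipped to [0, 65535]", clipped), call. = FALSE)
    }
    scan_frame(arr, dpi = dpi, metadata = meta)
  }
  pre <- make(rep(noise$I0_mean, 3L))
  post_levels <- vapply(CHANNELS, function(ch)
    noise$I0_mean * 10^(-eval_forward(truth, dose, ch)), numeric(1))
  post <- make(post_levels)
  list(pre = pre, post = post)
}

#' Simulate a full calibration dataset
#'
#' Runs the scan-pair simulator and the netOD stage for every dose in the
#' grid, for a number of replicate film pieces, producing the tidy table the
#' calibration fitter consumes.  The default dose grid is the standard
#' film-calibration ladder: 0.25 Gy steps up to 1 Gy, 1 Gy steps from 1 to
#' 10 Gy, then 2 Gy steps up to 20 Gy.
#'
#' @param truth A [calibration_truth()].
#' @param dose_grid Strictly increasing doses in Gy, all >= 0.
#' @param replicates Films per dose.
#' @param noise A [noise_spec()]; replicate pieces get sub-seeds derived
#'   from `noise$seed` so the whole dataset is reproducible.
#' @param shape Pixel extent of each simulated piece.
#' @param sigma_form Passed to [netod_triplet()].
#' @return A data.frame with `dose_gy`, `replicate`, `channel`, `netod`,
#'   `sigma`.
#' @export
simulate_calibration_dataset <- function(truth,
                                         dose_grid = default_dose_grid(),
                                         replicates = 1L,
                                         noise = noise_spec(),
                                         shape = c(32L, 32L),
                                         sigma_form = "standard") {
  assert_increasing(dose_grid, "dose_grid")
  if (any(dose_grid < 0)) stop_pf("doses must be >= 0")
  rows <- list()
  for (i in seq_along(dose_grid)) {
    for (r in seq_len(replicates)) {
      sub <- noise
      sub$seed <- derive_seed(noise$seed, i, r)
      pair <- simulate_scan_pair(dose_grid[i], truth, sub, shape)
      tri <- netod_triplet(pair$pre, pair$post, sigma_form = sigma_form)
      rows[[length(rows) + 1L]] <-
        cbind(dose_gy = dose_grid[i], replicate = r,
              tri[, c("channel", "netod", "sigma")])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname simulate_calibration_dataset
#' @export
default_dose_grid <- function() {
  c(seq(0.25, 1, by = 0.25), seq(2, 10, by = 1), seq(12, 20, by = 2))
}

# deterministic sub-seed, kept within 32-bit integer range
derive_seed <- function(seed, i, r = 1L) {
  as.integer((as.numeric(seed) * 7919 + i * 104729 + r * 1299709) %% .Machine$integer.max)
}

#' Simulate a post-irradiation darkening time series
#'
#' Evaluates the biexponential darkening model
#' `netOD(t) = netOD_inf - C1*exp(-t/T1) - C2*exp(-t/T2)` per channel on a
#' time grid and adds Gaussian noise with standard deviation
#' `noise_fraction * netOD_inf`.  The default grid is the usual film
#' stability protocol: 0, 0.5, 1, 2, 4, 8, 24, 48 and 120 hours.
#'
#' @param truth A [kinetics_truth()].
#' @param times Strictly increasing scan times in hours, all >= 0.
#' @param noise_fraction Additive noise as a fraction of `netOD_inf`.
#' @param seed Integer seed.
#' @return A data.frame with `time_h`, `netod_red`, `netod_green`,
#'   `netod_blue`.
#' @export
simulate_kinetics_series <- function(truth,
                                     times = c(0, 0.5, 1, 2, 4, 8, 24, 48, 120),
                                     noise_fraction = 0, seed = 1L) {
  stopifnot(inherits(truth, "kinetics_truth"))
  assert_increasing(times, "times")
  if (any(times < 0)) stop_pf("times must be >= 0")
  set.seed(as.integer(seed))
  out <- data.frame(time_h = times)
  for (ch in CHANNELS) {
    y <- biexp(times, truth$netod_inf[[ch]], truth$C1[[ch]], truth$T1[[ch]],
               truth$C2[[ch]], truth$T2[[ch]])
    if (noise_fraction > 0) {
      y <- y + noise_fraction * truth$netod_inf[[ch]] * stats::rnorm(length(times))
    }
    out[[paste0("netod_", ch)]] <- y
  }
  out
}

biexp <- function(t, netod_inf, C1, T1, C2, T2) {
  netod_inf - C1 * exp(-t / T1) - C2 * exp(-t / T2)
}

#' Simulate film and chamber depth-dose profiles
#'
#' Builds a parametric pristine Bragg curve as the chamber reference: an
#' entrance plateau with a slow linear rise that blends into a skewed peak —
#' a Gaussian rise of width `peak_sigma` on the proximal side and a steeper
#' Gaussian fall-off of width `distal_falloff_sigma` beyond the peak — with
#' the maximum exactly at `peak_depth` and the peak-to-plateau ratio of the
#' beam truth.  The film response applies a depth-ramped quench factor
#' `1 - q(z)`, where `q` rises linearly from 0 at `quench_onset` mm before
#' the peak to `quench_max` at and beyond the peak — the LET under-response
#' signature of radiochromic film.
#'
#' @param beam A [beam_truth()].
#' @param grid Strictly increasing depths in mm.
#' @return A list of [dose_profile()]s: `chamber`, `film_true_dose` (what an
#'   ideal film would read) and `film_response` (with quenching).
#' @export
simulate_depth_profiles <- function(beam = beam_truth(),
                                    grid = seq(0, 180, by = 1)) {
  stopifnot(inherits(beam, "beam_truth"))
  assert_increasing(grid, "grid")
  z <- grid
  chamber <- bragg_curve(z, beam)
  q <- quench_fraction(z, beam)
  film <- chamber * (1 - q)
  list(chamber = dose_profile(z, chamber, "depth", "chamber"),
       film_true_dose = dose_profile(z, chamber, "depth", "film-red"),
       film_response = dose_profile(z, film, "depth", "film-red"))
}

bragg_curve <- function(z, beam) {
  zp <- beam$peak_depth
  peak <- beam$entrance_plateau * beam$peak_to_plateau
  plateau <- beam$entrance_plateau * (1 + 0.002 * pmin(z, zp))
  g_prox <- exp(-(z - zp)^2 / (2 * beam$peak_sigma^2))
  g_dist <- exp(-(z - zp)^2 / (2 * beam$distal_falloff_sigma^2))
  # proximal: plateau blending into the peak; distal: Gaussian fall-off.
  # plateau < peak everywhere, so the global maximum sits exactly at zp.
  ifelse(z <= zp, plateau + (peak - plateau) * g_prox, peak * g_dist)
}

quench_fraction <- function(z, beam) {
  ramp <- (z - (beam$peak_depth - beam$quench_onset)) / beam$quench_onset
  beam$quench_max * pmin(pmax(ramp, 0), 1)
}

#' Simulate film and chamber lateral profiles
#'
#' A flat 2 * `field_half_width` field with error-function penumbrae of
#' width `penumbra_sigma`, normalized to 100 % on the central axis; by
#' construction the profile crosses 50 % at the nominal field edges.  The
#' film profile equals the chamber profile (film and chamber agree across
#' the penumbra at these depths) unless `film_scale` perturbs it.
#'
#' @param beam A [beam_truth()].
#' @param grid Strictly increasing lateral positions in mm; must extend
#'   beyond the field edges so the penumbra is sampled.
#' @param film_scale Optional multiplicative perturbation applied to the
#'   film profile (scalar or one value per grid point).
#' @return A list of [dose_profile()]s: `chamber` and `film_response`, in %
#'   of the central-axis value.
#' @export
simulate_lateral_profiles <- function(beam = beam_truth(),
                                      grid = seq(-70, 70, by = 1),
                                      film_scale = 1) {
  stopifnot(inherits(beam, "beam_truth"))
  assert_increasing(grid, "grid")
  w <- beam$field_half_width
  if (min(grid) > -w || max(grid) < w) {
    stop_pf("grid must extend beyond +/-%g mm so the penumbra is sampled", w)
  }
  s <- beam$penumbra_sigma
  shape <- function(x) 0.5 * (erf((x + w) / (sqrt(2) * s)) - erf((x - w) / (sqrt(2) * s)))
  vals <- 100 * shape(grid) / shape(0)
  film <- vals * rep_len(film_scale, length(grid))
  list(chamber = dose_profile(grid, vals, "lateral", "chamber"),
       film_response = dose_profile(grid, film, "lateral", "film-red"))
}
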