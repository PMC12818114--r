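#' Symmetric percent difference
#'
#' The shared kernel for reproducibility and batch-variation statistics:
#' `100 * |x - y| / mean(x, y)`.  Symmetric in its arguments.
#'
#' @param x,y Positive values (vectorized).
#' @return Percent difference(s).
#' @export
percent_difference <- function(x, y) {
  if (any(x <= 0) || any(y <= 0)) stop_pf("percent_difference needs positive inputs")
  100 * abs(x - y) / ((x + y) / 2)
}

#' Measurement groups
#'
#' A `measurement_group` collects the netOD triplets of films irradiated
#' under one condition (one energy, one session day, or one batch) at a
#' common nominal dose.
#'
#' @param label Condition label (e.g. `"150 MeV"`, `"day1"`, `"B1"`).
#' @param dose_gy Common nominal dose in Gy.
#' @param triplets A data.frame of netOD rows with columns `channel`,
#'   `netod` (and optionally `sigma`), e.g. stacked [netod_triplet()]
#'   outputs.
#' @return An object of class `measurement_group`.
#' @export
measurement_group <- function(label, dose_gy, triplets) {
  if (!all(c("channel", "netod") %in% names(triplets)) || nrow(triplets) == 0L) {
    stop_pf("`triplets` must be a non-empty data.frame with channel and netod")
  }
  assert_scalar_num(dose_gy, "dose_gy", 0)
  structure(list(label = as.character(label), dose_gy = dose_gy,
                 triplets = triplets),
            class = "measurement_group")
}

group_means <- function(group) {
  vapply(CHANNELS, function(ch) {
    v <- group$triplets$netod[group$triplets$channel == ch]
    if (length(v) == 0L) NA_real_ else mean(v)
  }, numeric(1))
}

#' Day-to-day reproducibility
#'
#' Symmetric percent difference of the session-mean netOD between two
#' measurement sessions at the same delivered dose, per channel.
#'
#' @param day1,day2 [measurement_group()]s at a matched dose.
#' @return Named numeric vector of percent differences per channel.
#' @export
reproducibility <- function(day1, day2) {
  stopifnot(inherits(day1, "measurement_group"), inherits(day2, "measurement_group"))
  if (!isTRUE(all.equal(day1$dose_gy, day2$dose_gy))) {
    stop_pf("sessions were delivered different doses (%g vs %g Gy)",
            day1$dose_gy, day2$dose_gy)
  }
  m1 <- group_means(day1); m2 <- group_means(day2)
  stats::setNames(percent_difference(m1, m2), CHANNELS)
}

#' Energy dependence of the film response
#'
#' The maximum percent deviation of per-energy mean netOD from the grand
#' mean across energy groups, per channel:
#' `100 * max_g |mean_g - grand_mean| / grand_mean`.
#' For an energy-independent film this statistic stays within the
#' measurement noise.
#'
#' @param groups A list of >= 2 [measurement_group()]s (one per beam
#'   energy) at a fixed dose.
#' @return Named numeric vector of max percent deviations per channel.
#' @export
energy_dependence <- function(groups) {
  if (length(groups) < 2L) stop_pf("need >= 2 energy groups")
  for (g in groups) stopifnot(inherits(g, "measurement_group"))
  doses <- vapply(groups, function(g) g$dose_gy, numeric(1))
  if (diff(range(doses)) > 1e-9) stop_pf("groups must share a common dose")
  means <- vapply(groups, group_means, numeric(3))  # channels x groups
  grand <- rowMeans(means)
  if (any(grand <= 0)) stop_pf("grand mean netOD must be > 0")
  stats::setNames(100 * apply(abs(means - grand), 1, max) / grand, CHANNELS)
}

#' Sensitivity deviation from the calibration prediction
#'
#' Percent deviation of a measured netOD from the value the fitted
#' dose-response predicts at the delivered dose:
#' `100 * (measured - predicted) / predicted`.  Signed, normalized by the
#' prediction.
#'
#' @param measured A netOD triplet data.frame (columns `channel`, `netod`).
#' @param model A [fit_calibration()] model.
#' @param delivered Delivered dose in Gy, > 0 and within the fitted range.
#' @return Named numeric vector of signed percent deviations per channel.
#' @export
sensitivity_deviation <- function(measured, model, delivered) {
  if (delivered <= 0) stop_pf("delivered dose must be > 0 (zero prediction)")
  vapply(CHANNELS, function(ch) {
    pred <- eval_forward(model, delivered, ch)
    obs <- measured$netod[measured$channel == ch]
    if (length(obs) == 0L) return(NA_real_)
    100 * (mean(obs) - pred) / pred
  }, numeric(1))
}

#' Can two doses be resolved above the measurement noise?
#'
#' Two doses are called resolvable when their predicted netOD separation
#' exceeds `k * sqrt(2) * sigma_netod` — the separation criterion for two
#' measurements of equal uncertainty; `k = 2` corresponds to about 95 %
#' two-sided confidence.
#'
#' @param doseA,doseB Doses in Gy within the fitted range.
#' @param model A [fit_calibration()] model (or a [calibration_truth()]).
#' @param sigma_netod Per-measurement netOD uncertainty (scalar or named
#'   per channel), >= 0.
#' @param k Separation multiple, default 2.
#' @return Named logical vector per channel.
#' @export
resolvable <- function(doseA, doseB, model, sigma_netod, k = 2) {
  if (any(sigma_netod < 0)) stop_pf("sigma_netod must be >= 0")
  sig <- if (length(sigma_netod) == 1L)
    stats::setNames(rep(sigma_netod, 3L), CHANNELS) else sigma_netod[CHANNELS]
  vapply(CHANNELS, function(ch) {
    dnet <- abs(eval_forward(model, doseA, ch) - eval_forward(model, doseB, ch))
    dnet > k * sqrt(2) * sig[[ch]]
  }, logical(1))
}

#' Batch-to-batch variation
#'
#' Symmetric percent difference of mean measured netOD between two film
#' batches at a common dose, per channel.
#'
#' @param groupA,groupB [measurement_group()]s (one per batch) at a common
#'   dose.
#' @return Named numeric vector of percent differences per channel.
#' @export
batch_variation <- function(groupA, groupB) {
  reproducibility(groupA, groupB)
}

#' Mean noise-to-signal ratio of a calibration dataset
#'
#' Mean over doses of `100 * sigma / netod` per channel, excluding zero
#' dose and (with a warning) any non-positive netOD.  Orders the channels
#' by dosimetric quality: red lowest, blue highest.
#'
#' @param dataset A calibration table with columns `dose_gy`, `channel`,
#'   `netod`, `sigma` (see [simulate_calibration_dataset()]).
#' @return Named numeric vector of mean NSR (%) per channel.
#' @export
noise_to_signal <- function(dataset) {
  if (!all(c("dose_gy", "channel", "netod", "sigma") %in% names(dataset))) {
    stop_pf("dataset needs columns dose_gy, channel, netod, sigma")
  }
  keep <- dataset$dose_gy > 0
  bad <- keep & dataset$netod <= 0
  if (any(bad)) {
    warning(sprintf("%d non-positive netOD value(s) excluded from NSR", sum(bad)),
            call. = FALSE)
    keep <- keep & !bad
  }
  d <- dataset[keep, ]
  vapply(CHANNELS, function(ch) {
    sub <- d[d$channel == ch, ]
    if (nrow(sub) == 0L) return(NA_real_)
    mean(100 * sub$sigma / sub$netod)
  }, numeric(1))
}
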