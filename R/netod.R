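#' Net optical density from paired scans
#'
#' netOD is the film's dose surrogate: the base-10 log of the ratio of
#' unexposed (`I0`) to exposed (`I`) transmission signal,
#' `netOD = log10(I0 / I)`.  Its uncertainty propagates the relative errors
#' of the two signals.  Two sigma conventions are provided:
#'
#' * `"standard"` (default): `sigma = (1/ln 10) * sqrt((s0/I0)^2 + (s/I)^2)`,
#'   the plain first-order propagation of the log-ratio, which keeps a
#'   finite noise floor as netOD approaches 0;
#' * `"scaled"`: the same quantity multiplied by netOD, a convention that
#'   appears in parts of the film literature; it vanishes at netOD = 0.
#'
#' By default the signal errors `s0`, `s` are the standard errors of the ROI
#' means (`sd / sqrt(n)`), since the ROI mean is the estimator entering
#' netOD; set `pixel_sd = TRUE` to use raw pixel standard deviations
#' instead (a per-pixel noise figure rather than a mean uncertainty).
#'
#' @param pre,post Single-channel statistics: one row of [roi_stats()]
#'   output, or any list with `mean`, `sd`, `n`.
#' @param sigma_form `"standard"` or `"scaled"`.
#' @param pixel_sd Use pixel sd instead of the standard error of the mean.
#' @return A one-row data.frame with `netod`, `sigma`, `sigma_form`.
#' @export
compute_netod <- function(pre, post, sigma_form = c("standard", "scaled"),
                          pixel_sd = FALSE) {
  sigma_form <- match.arg(sigma_form)
  if (pre$mean <= 0 || post$mean <= 0) {
    stop_pf("channel means must be > 0 to form netOD")
  }
  netod <- log10(pre$mean / post$mean)
  div <- function(s) if (pixel_sd) 1 else sqrt(s)
  rel0 <- (pre$sd / div(pre$n)) / pre$mean
  rel1 <- (post$sd / div(post$n)) / post$mean
  sigma <- sqrt(rel0^2 + rel1^2) / log(10)
  if (sigma_form == "scaled") sigma <- abs(netod) * sigma
  # a post-scan lighter than baseline beyond the noise floor is a bad pair
  if (netod < 0 && abs(netod) > 3 * max(sigma, .Machine$double.eps)) {
    stop_pf("film lighter than baseline: netOD = %.4g with sigma = %.4g", netod, sigma)
  }
  data.frame(netod = netod, sigma = sigma, sigma_form = sigma_form)
}

#' Per-channel netOD triplet for one film piece
#'
#' Applies [roi_stats()] to a pre/post scan pair and [compute_netod()] per
#' channel.
#'
#' @param pre,post [scan_frame()]s of the same film piece before and after
#'   irradiation.
#' @param roi ROI used on both frames; defaults to the central 50 % region
#'   of the pre frame.
#' @inheritParams compute_netod
#' @return A data.frame with one row per channel: `channel`, `netod`,
#'   `sigma`, `sigma_form`.
#' @export
netod_triplet <- function(pre, post, roi = central_roi(pre),
                          sigma_form = c("standard", "scaled"),
                          pixel_sd = FALSE) {
  sigma_form <- match.arg(sigma_form)
  s0 <- roi_stats(pre, roi)
  s1 <- roi_stats(post, roi)
  out <- lapply(seq_along(CHANNELS), function(k) {
    cbind(channel = CHANNELS[k],
          compute_netod(s0[k, ], s1[k, ], sigma_form, pixel_sd))
  })
  do.call(rbind, out)
}

#' Per-pixel netOD map
#'
#' Elementwise `log10(pre / post)` for each channel.  Pixels where the post
#' signal is zero (full attenuation or dead pixel) cannot form a log-ratio
#' and are returned as `NA`.
#'
#' @param pre,post [scan_frame()]s with identical dimensions.
#' @return A numeric `height x width x 3` array of netOD values with `NA`
#'   marking invalid pixels; carries the input `dpi` as attribute `"dpi"`.
#' @export
netod_map <- function(pre, post) {
  stopifnot(inherits(pre, "scan_frame"), inherits(post, "scan_frame"))
  if (!identical(frame_dims(pre), frame_dims(post))) {
    stop_pf("pre and post frames differ in dimensions")
  }
  out <- array(NA_real_, dim = dim(pre$data))
  ok <- post$data > 0 & pre$data > 0
  out[ok] <- log10(pre$data[ok] / post$data[ok])
  attr(out, "dpi") <- pre$dpi
  out
}

#' Extract a 1-D profile from a netOD map
#'
#' Averages a central band of rows (depth axis) or columns (lateral axis) of
#' one channel of a netOD map and converts pixel indices to millimetres via
#' the scan resolution (pixel pitch = 25.4 / dpi mm).  Positions are
#' centered on the raster midline.
#'
#' @param map Output of [netod_map()] (or any raster array).
#' @param channel `"red"`, `"green"` or `"blue"`.
#' @param axis `"depth"` profiles along image columns (x); `"lateral"`
#'   profiles along image rows (y).
#' @param band_halfwidth The band averaged at each position has
#'   `2 * band_halfwidth + 1` pixels.
#' @param dpi Resolution override; defaults to the map's `"dpi"` attribute.
#' @return A [dose_profile()] of netOD values (`source` left as the channel
#'   name).
#' @export
extract_profile <- function(map, channel = "red", axis = c("depth", "lateral"),
                            band_halfwidth = 2, dpi = attr(map, "dpi") %||% 300) {
  axis <- match.arg(axis)
  channel <- match_channel(channel)
  k <- match(channel, CHANNELS)
  ras <- map[, , k]
  d <- dim(ras)
  across <- if (axis == "depth") d[1] else d[2]
  mid <- ceiling(across / 2)
  band <- (mid - band_halfwidth):(mid + band_halfwidth)
  if (band[1] < 1 || band[length(band)] > across) {
    stop_pf("band of %d px exceeds the raster (%d px across)",
            2 * band_halfwidth + 1, across)
  }
  vals <- if (axis == "depth") colMeans(ras[band, , drop = FALSE])
          else rowMeans(ras[, band, drop = FALSE])
  pitch <- 25.4 / dpi
  pos <- (seq_along(vals) - (length(vals) + 1) / 2) * pitch
  dose_profile(pos, vals, geometry = axis, source = paste0("film-", channel))
}
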