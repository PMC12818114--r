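#' Dose profiles
#'
#' Ordered (position, value) samples of a dose distribution along the beam
#' axis (`geometry = "depth"`, positions in mm water-equivalent depth) or
#' across the field (`geometry = "lateral"`, positions in mm offset from
#' the central axis).  Values are dose (Gy), netOD, or percent of the
#' central-axis value after [normalize_central_axis()].
#'
#' @param positions Strictly increasing positions in mm.
#' @param values Non-negative profile values, same length.
#' @param geometry `"depth"` or `"lateral"`.
#' @param source Measurement source: `"chamber"`, `"film-red"`,
#'   `"film-green"` or `"film-blue"`.
#' @return An object of class `dose_profile` (a data.frame with columns
#'   `position_mm`, `value` and attributes `geometry`, `source`).
#' @export
dose_profile <- function(positions, values,
                         geometry = c("depth", "lateral"),
                         source = c("chamber", "film-red", "film-green", "film-blue")) {
  geometry <- match.arg(geometry)
  source <- match.arg(source)
  assert_increasing(positions, "positions")
  if (length(values) != length(positions)) {
    stop_pf("positions and values differ in length")
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop_pf("profile values must be finite and >= 0")
  }
  structure(data.frame(position_mm = as.numeric(positions),
                       value = as.numeric(values)),
            geometry = geometry, source = source,
            class = c("dose_profile", "data.frame"))
}

profile_meta <- function(p) list(geometry = attr(p, "geometry"),
                                 source = attr(p, "source"))

#' Resample a profile onto a new position grid
#'
#' Linear interpolation; the target grid must lie within the profile's
#' span (no extrapolation).
#'
#' @param profile A [dose_profile()].
#' @param grid Strictly increasing positions in mm inside the profile span.
#' @return A [dose_profile()] on `grid`.
#' @export
resample <- function(profile, grid) {
  stopifnot(inherits(profile, "dose_profile"))
  assert_increasing(grid, "grid")
  rng <- range(profile$position_mm)
  if (min(grid) < rng[1] || max(grid) > rng[2]) {
    stop_pf("grid [%g, %g] mm extends beyond the profile span [%g, %g] mm",
            min(grid), max(grid), rng[1], rng[2])
  }
  v <- stats::approx(profile$position_mm, profile$value, xout = grid)$y
  m <- profile_meta(profile)
  dose_profile(grid, v, m$geometry, m$source)
}

#' Pointwise relative dose difference between film and chamber
#'
#' The profile-comparison statistic `100 * (film / chamber - 1)` on a
#' common grid: negative where the film under-responds.  Points where the
#' chamber reads zero cannot be compared and are returned as `NA`; points
#' where the chamber dose is below `min_fraction` of its maximum (deep in
#' the distal fall-off, where film/chamber matching is not meaningful) are
#' flagged in the `reliable` column.
#'
#' @param film,chamber [dose_profile()]s on a common grid ([resample()]
#'   first if needed).
#' @param min_fraction Chamber threshold (fraction of chamber maximum)
#'   below which points are flagged unreliable; default 0.01.
#' @return A data.frame with `position_mm`, `diff_pct`, `reliable`.
#' @export
relative_dose_difference <- function(film, chamber, min_fraction = 0.01) {
  stopifnot(inherits(film, "dose_profile"), inherits(chamber, "dose_profile"))
  if (!isTRUE(all.equal(film$position_mm, chamber$position_mm))) {
    stop_pf("film and chamber must share a common grid; resample() first")
  }
  d <- rep(NA_real_, nrow(film))
  ok <- chamber$value > 0
  d[ok] <- 100 * (film$value[ok] / chamber$value[ok] - 1)
  data.frame(position_mm = film$position_mm, diff_pct = d,
             reliable = ok & chamber$value >= min_fraction * max(chamber$value))
}

#' Normalize a lateral profile to its central-axis value
#'
#' Scales a profile so its value at position 0 (linearly interpolated if 0
#' is not a sample) equals 100 %.  Idempotent; shape- and
#' asymmetry-preserving.
#'
#' @param profile A [dose_profile()] spanning position 0.
#' @return The normalized [dose_profile()] in % of the central-axis value.
#' @export
normalize_central_axis <- function(profile) {
  stopifnot(inherits(profile, "dose_profile"))
  rng <- range(profile$position_mm)
  if (rng[1] > 0 || rng[2] < 0) stop_pf("profile must span position 0")
  v0 <- stats::approx(profile$position_mm, profile$value, xout = 0)$y
  if (!is.finite(v0) || v0 <= 0) stop_pf("central-axis value must be > 0")
  m <- profile_meta(profile)
  dose_profile(profile$position_mm, 100 * profile$value / v0,
               m$geometry, m$source)
}

#' Positions where a lateral profile crosses given dose levels
#'
#' Searches outward from the field center along one shoulder of a profile
#' in % of central axis and returns, for each level, the position where
#' the profile first crosses it (linear interpolation between samples).
#' Standard penumbra metrics use the 50/20/5 % levels.  A level never
#' crossed is returned as `NA`.
#'
#' @param profile A [dose_profile()] in % of central axis.
#' @param levels Levels in %, e.g. `c(50, 20, 5)`.
#' @param side `"positive"` or `"negative"` shoulder.
#' @return Named numeric vector of crossing positions in mm.
#' @export
level_crossings <- function(profile, levels = c(50, 20, 5),
                            side = c("positive", "negative")) {
  stopifnot(inherits(profile, "dose_profile"))
  side <- match.arg(side)
  pos <- profile$position_mm
  val <- profile$value
  if (side == "negative") { pos <- rev(-pos); val <- rev(val) }
  keep <- pos >= 0
  pos <- pos[keep]; val <- val[keep]
  out <- vapply(levels, function(lv) {
    if (val[1] <= lv) return(if (val[1] == lv) pos[1] else NA_real_)
    below <- which(val <= lv)
    if (length(below) == 0L) return(NA_real_)
    j <- below[1]
    # interpolate between the last sample above and the first at/below
    x <- pos[(j - 1):j]; y <- val[(j - 1):j]
    x[1] + (lv - y[1]) * (x[2] - x[1]) / (y[2] - y[1])
  }, numeric(1))
  sgn <- if (side == "negative") -1 else 1
  stats::setNames(sgn * out, paste0("L", levels))
}

#' Film-vs-chamber deviation table at penumbra positions
#'
#' For each requested lateral position, reports the chamber and film
#' values (% of central axis) and their difference in percentage points
#' (film - chamber) — the presentation conventional for penumbra
#' comparisons.  Both profiles must already be normalized to the central
#' axis (value 100 at position 0 within 0.1).
#'
#' @param film,chamber Normalized [dose_profile()]s.
#' @param positions Lateral positions in mm within both spans.
#' @return A data.frame with `position_mm`, `chamber_pct`, `film_pct`,
#'   `deviation_pp`, `deviation_rel_pct` (the relative form,
#'   `100*(film/chamber - 1)`).
#' @export
lateral_deviation_table <- function(film, chamber, positions) {
  for (p in list(film, chamber)) {
    v0 <- stats::approx(p$position_mm, p$value, xout = 0)$y
    if (!is.finite(v0) || abs(v0 - 100) > 0.1) {
      stop_pf("profiles must be normalized to 100%% at the central axis (got %.3g)", v0)
    }
  }
  f <- resample(film, positions)$value
  c_ <- resample(chamber, positions)$value
  data.frame(position_mm = positions, chamber_pct = c_, film_pct = f,
             deviation_pp = f - c_,
             deviation_rel_pct = ifelse(c_ > 0, 100 * (f / c_ - 1), NA_real_))
}

#' Film under-response at the Bragg peak
#'
#' The mean relative dose difference `100 * (film/chamber - 1)` over a
#' window centered on the chamber-maximum depth — the scalar summary of
#' LET quenching at the peak (negative for under-response).
#'
#' @param film,chamber Depth [dose_profile()]s on a common grid covering
#'   the chamber maximum.
#' @param window Half-width of the averaging window in mm, default 1.
#' @return Mean percent difference at the peak.
#' @export
peak_under_response <- function(film, chamber, window = 1) {
  stopifnot(inherits(film, "dose_profile"), inherits(chamber, "dose_profile"))
  if (window < 0) stop_pf("window must be >= 0")
  z_peak <- chamber$position_mm[which.max(chamber$value)]
  dd <- relative_dose_difference(film, chamber)
  sel <- abs(dd$position_mm - z_peak) <= window & !is.na(dd$diff_pct)
  if (!any(sel)) stop_pf("no grid points within %g mm of the peak at %g mm", window, z_peak)
  mean(dd$diff_pct[sel])
}

#' Write or read a profile as CSV
#'
#' Columns `position_mm,value,source,geometry`.
#'
#' @param profile A [dose_profile()].
#' @param path CSV path.
#' @export
write_profile_csv <- function(profile, path) {
  m <- profile_meta(profile)
  utils::write.csv(cbind(profile, source = m$source, geometry = m$geometry),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  x <- utils::read.csv(path)
  dose_profile(x$position_mm, x$value, x$geometry[1], x$source[1])
}
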