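#' Ground-truth parameter objects for the synthetic-data generator
#'
#' The simulators in this package are driven by small "truth" objects holding
#' the parameters of the generating models: the per-channel rational
#' dose-response of a film batch, the biexponential darkening kinetics, the
#' parametric proton beam used for depth and lateral profiles, and the scanner
#' noise model.  Each constructor validates its invariants and returns a
#' classed list.
#'
#' @param film_model Film product label, `"EBT3"` or `"EBT4"`.
#' @param batch Batch (production lot) label, e.g. `"B1"`.
#' @param a,b,n Named numeric vectors over channels `red`, `green`, `blue`
#'   with the forward dose-response parameters of `netOD = a*D / (1 + b*D^n)`:
#'   `a` (netOD per Gy scale, > 0), `b` (Gy^-n scale, >= 0) and the
#'   dimensionless exponent `n` (> 0).
#' @return An object of class `calibration_truth`.
#' @seealso [preset_truth()] for the built-in batch presets.
#' @export
calibration_truth <- function(film_model, batch, a, b, n) {
  film_model <- match.arg(film_model, c("EBT3", "EBT4"))
  a <- a[CHANNELS]; b <- b[CHANNELS]; n <- n[CHANNELS]
  if (any(is.na(a)) || any(is.na(b)) || any(is.na(n))) {
    stop_pf("`a`, `b`, `n` must each be named over channels %s",
            paste(CHANNELS, collapse = ", "))
  }
  if (any(a <= 0)) stop_pf("all `a` must be > 0")
  if (any(b < 0)) stop_pf("all `b` must be >= 0")
  if (any(n <= 0)) stop_pf("all `n` must be > 0")
  truth <- structure(
    list(film_model = film_model, batch = as.character(batch),
         a = a, b = b, n = n),
    class = "calibration_truth")
  # monotone response on the working dose range is part of the contract
  d <- seq(0.01, 20, by = 0.01)
  for (ch in CHANNELS) {
    y <- rational_response(d, a[[ch]], b[[ch]], n[[ch]])
    if (any(diff(y) <= 0)) {
      stop_pf("forward curve for channel %s is not strictly increasing on (0, 20] Gy", ch)
    }
  }
  truth
}

# forward rational dose-response kernel (shared with the calibration module)
rational_response <- function(dose, a, b, n) a * dose / (1 + b * dose^n)

#' Built-in film batch calibration presets
#'
#' Returns the per-channel rational dose-response parameters for one of the
#' characterized film batches: `B1` and `B2` (EBT4 lots) and `B4` (an EBT3
#' lot).  These parameter sets drive the synthetic scanner simulations and
#' serve as recovery targets for calibration round-trip tests.
#'
#' @param batch_id One of `"B1"`, `"B2"`, `"B4"`.
#' @return A [calibration_truth()] object.
#' @examples
#' preset_truth("B1")$a[["red"]]   # 0.0740
#' @export
preset_truth <- function(batch_id) {
  presets <- list(
    B1 = list(film = "EBT4",
              a = c(red = 0.0740, green = 0.0418, blue = 0.0142),
              b = c(red = 0.0842, green = 0.0258, blue = 0.0004),
              n = c(red = 0.9684, green = 1.0355, blue = 2.1124)),
    B2 = list(film = "EBT4",
              a = c(red = 0.1084, green = 0.0532, blue = 0.0205),
              b = c(red = 0.2339, green = 0.0959, blue = 0.0593),
              n = c(red = 0.7978, green = 0.7919, blue = 0.8161)),
    B4 = list(film = "EBT3",
              a = c(red = 0.1844, green = 0.0912, blue = 0.0393),
              b = c(red = 0.5289, green = 0.2252, blue = 0.2132),
              n = c(red = 0.7403, green = 0.7597, blue = 0.6624)))
  if (!is.character(batch_id) || length(batch_id) != 1L ||
      !batch_id %in% names(presets)) {
    stop_pf("unknown batch '%s'; available presets: %s",
            as.character(batch_id)[1], paste(names(presets), collapse = ", "))
  }
  p <- presets[[batch_id]]
  calibration_truth(p$film, batch_id, p$a, p$b, p$n)
}

#' @rdname calibration_truth
#' @param netod_inf Per-channel saturation netOD (named over channels or a
#'   single value recycled), > 0.
#' @param C1,C2 Amplitudes (dimensionless, >= 0) of the fast and slow
#'   darkening components.
#' @param T1,T2 Time constants in hours (> 0) of the two components.
#' @export
kinetics_truth <- function(netod_inf, C1, T1, C2, T2) {
  rec <- function(x, name) {
    if (length(x) == 1L) x <- stats::setNames(rep(x, 3L), CHANNELS)
    x <- x[CHANNELS]
    if (any(is.na(x))) stop_pf("`%s` must be named over channels or scalar", name)
    x
  }
  netod_inf <- rec(netod_inf, "netod_inf")
  C1 <- rec(C1, "C1"); T1 <- rec(T1, "T1")
  C2 <- rec(C2, "C2"); T2 <- rec(T2, "T2")
  if (any(netod_inf <= 0)) stop_pf("netod_inf must be > 0")
  if (any(C1 < 0) || any(C2 < 0)) stop_pf("amplitudes C1, C2 must be >= 0")
  if (any(T1 <= 0) || any(T2 <= 0)) stop_pf("time constants T1, T2 must be > 0")
  if (any(netod_inf - C1 - C2 < 0)) {
    stop_pf("netod_inf - C1 - C2 must be >= 0 (netOD at t = 0 cannot be negative)")
  }
  structure(list(netod_inf = netod_inf, C1 = C1, T1 = T1, C2 = C2, T2 = T2),
            class = "kinetics_truth")
}

#' @rdname calibration_truth
#' @param entrance_plateau Relative dose level of the entrance plateau.
#' @param peak_depth Bragg-peak depth in mm (water-equivalent).
#' @param peak_sigma Proximal Gaussian width of the peak, mm.
#' @param peak_to_plateau Peak-to-entrance dose ratio (> 1).
#' @param distal_falloff_sigma Distal fall-off width, mm.
#' @param field_half_width Lateral half-width of the uniform field, mm.
#' @param penumbra_sigma Lateral penumbra (error-function shoulder) width, mm.
#' @param quench_max Fractional film under-response at and beyond the peak,
#'   in `[0, 1)`.
#' @param quench_onset Distance before the peak, mm, where the under-response
#'   ramp starts.
#' @export
beam_truth <- function(entrance_plateau = 1, peak_depth = 157, peak_sigma = 6,
                       peak_to_plateau = 3.5, distal_falloff_sigma = 1.5,
                       field_half_width = 50, penumbra_sigma = 3,
                       quench_max = 0.18, quench_onset = 15) {
  assert_scalar_num(entrance_plateau, "entrance_plateau", 0, strict_min = TRUE)
  assert_scalar_num(peak_depth, "peak_depth", 0, strict_min = TRUE)
  assert_scalar_num(peak_sigma, "peak_sigma", 0, strict_min = TRUE)
  assert_scalar_num(distal_falloff_sigma, "distal_falloff_sigma", 0, strict_min = TRUE)
  assert_scalar_num(field_half_width, "field_half_width", 0, strict_min = TRUE)
  assert_scalar_num(penumbra_sigma, "penumbra_sigma", 0, strict_min = TRUE)
  assert_scalar_num(quench_onset, "quench_onset", 0, strict_min = TRUE)
  if (peak_to_plateau <= 1) stop_pf("peak_to_plateau must be > 1")
  if (quench_max < 0 || quench_max >= 1) stop_pf("quench_max must be in [0, 1)")
  structure(list(entrance_plateau = entrance_plateau, peak_depth = peak_depth,
                 peak_sigma = peak_sigma, peak_to_plateau = peak_to_plateau,
                 distal_falloff_sigma = distal_falloff_sigma,
                 field_half_width = field_half_width,
                 penumbra_sigma = penumbra_sigma, quench_max = quench_max,
                 quench_onset = quench_onset),
            class = "beam_truth")
}

#' @rdname calibration_truth
#' @param fraction Per-channel multiplicative intensity noise fraction
#'   (named over channels or scalar), >= 0.  Defaults reproduce the red <
#'   green < blue noise ordering of transmission film scans.
#' @param I0_mean Mean unexposed-film scanner signal in 16-bit counts.
#' @param seed Integer seed making every simulation reproducible.
#' @export
noise_spec <- function(fraction = c(red = 0.010, green = 0.016, blue = 0.038),
                       I0_mean = 42000, seed = 1L) {
  if (length(fraction) == 1L) fraction <- stats::setNames(rep(fraction, 3L), CHANNELS)
  fraction <- fraction[CHANNELS]
  if (any(is.na(fraction)) || any(fraction < 0)) {
    stop_pf("noise `fraction` must be non-negative, named over channels or scalar")
  }
  assert_scalar_num(I0_mean, "I0_mean", 0, strict_min = TRUE)
  if (I0_mean > 65535) stop_pf("I0_mean must be <= 65535 (16-bit counts)")
  structure(list(fraction = fraction, I0_mean = I0_mean,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

#' Write or read a truth object as JSON
#'
#' @param truth A truth object from [calibration_truth()], [kinetics_truth()]
#'   or [beam_truth()].
#' @param path File path.
#' @return `read_truth_json()` returns the reconstructed truth object.
#' @export
write_truth_json <- function(truth, path) {
  x <- unclass(truth)
  # named numeric vectors must serialize as JSON objects, not bare arrays
  x <- lapply(x, function(v)
    if (is.numeric(v) && !is.null(names(v))) as.list(v) else v)
  x$.class <- class(truth)[1]
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- x$.class
  x$.class <- NULL
  switch(cls,
    calibration_truth = calibration_truth(x$film_model, x$batch,
                                          unlist(x$a), unlist(x$b), unlist(x$n)),
    kinetics_truth = kinetics_truth(unlist(x$netod_inf), unlist(x$C1),
                                    unlist(x$T1), unlist(x$C2), unlist(x$T2)),
    beam_truth = do.call(beam_truth, x),
    noise_spec = noise_spec(unlist(x$fraction), x$I0_mean, x$seed),
    stop_pf("unrecognized truth class in '%s'", path))
}
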