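#' Biexponential darkening model
#'
#' Radiochromic film continues to darken after irradiation as polymerization
#' proceeds.  The netOD growth is modeled as
#' `netOD(t) = netOD_inf - C1*exp(-t/T1) - C2*exp(-t/T2)`: a saturation
#' value approached through a fast and a slow exponential component.  The
#' model is nondecreasing in time and reaches `netOD_inf - C1 - C2` at
#' `t = 0`.
#'
#' @param model A list with `netod_inf`, `C1`, `T1`, `C2`, `T2` (one
#'   channel), e.g. one element of a [fit_biexponential()] result.
#' @param t Time(s) in hours, >= 0.
#' @return netOD value(s).
#' @export
eval_kinetics <- function(model, t) {
  if (any(t < 0)) stop_pf("t must be >= 0")
  biexp(t, model$netod_inf, model$C1, model$T1, model$C2, model$T2)
}

#' Fit the biexponential darkening model to a time series
#'
#' Damped (Levenberg-Marquardt) least squares with a multi-start over time
#' constants `T1 in {0.5, 2, 8}` h and `T2 in {12, 24, 72}` h; amplitude
#' starts are derived from the endpoint deficits (`netod_inf` from the last
#' sample, `C1 + C2` from the deficit at t = 0).  Biexponentials are
#' notoriously ill-conditioned, so the best final SSE across starts wins.
#' Fitted parameters are canonicalized to `T1 <= T2`.  Fits with RMSE >=
#' 1e-3 are flagged (`rmse_ok = FALSE`) as not meeting the usual quality
#' gate.
#'
#' @param times Scan times in hours, strictly increasing, >= 5 points with
#'   at least one at or beyond 24 h.
#' @param netods netOD values, same length.
#' @return A list with `netod_inf`, `C1`, `T1`, `C2`, `T2`, `rmse`,
#'   `rmse_ok`.
#' @export
fit_biexponential <- function(times, netods) {
  assert_increasing(times, "times")
  if (length(times) < 5L) stop_pf("need >= 5 time points")
  if (max(times) < 24) stop_pf("need at least one sample at or beyond 24 h")
  if (length(netods) != length(times)) stop_pf("times and netods differ in length")
  y_inf0 <- max(netods[length(netods)], 1e-6)
  deficit <- max(y_inf0 - netods[1], 1e-3)
  resid_fn <- function(p) {
    netods - (p[1] - p[2] * exp(-times / p[3]) - p[4] * exp(-times / p[5]))
  }
  best <- NULL; diagnostics <- character()
  for (T10 in c(0.5, 2, 8)) for (T20 in c(12, 24, 72)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = c(yi = y_inf0, c1 = 0.6 * deficit, t1 = T10,
                c2 = 0.4 * deficit, t2 = T20),
        lower = c(1e-9, 0, 1e-3, 0, 1e-3),
        fn = resid_fn,
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                             ptol = 1e-12)),
      error = function(e) {
        diagnostics <<- c(diagnostics,
                          sprintf("start (T1=%g, T2=%g): %s", T10, T20,
                                  conditionMessage(e)))
        NULL
      })
    if (is.null(fit)) next
    sse <- sum(resid_fn(fit$par)^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best)) {
    stop_pf("biexponential fit failed from every start:\n%s",
            paste(diagnostics, collapse = "\n"))
  }
  cf <- as.list(best$fit$par)
  out <- list(netod_inf = cf$yi, C1 = cf$c1, T1 = cf$t1, C2 = cf$c2, T2 = cf$t2)
  if (out$T1 > out$T2) {  # canonical ordering: fast component first
    out[c("C1", "T1", "C2", "T2")] <- out[c("C2", "T2", "C1", "T1")]
  }
  out$rmse <- sqrt(best$sse / length(netods))
  out$rmse_ok <- out$rmse < 1e-3
  out
}

#' Differential growth rate of a darkening series
#'
#' The model-independent rate statistic: the time derivative of netOD,
#' normalized to the 48-hour netOD and expressed in %/h (positive while the
#' film darkens),
#' `rate(t) = 100 * (dnetOD/dt) / netOD(48 h)`.
#' The derivative is computed by three-point Lagrange differentiation on
#' the (generally nonuniform) time grid, with one-sided two-point formulas
#' at the endpoints; this is exact for locally linear data.  The 48-h
#' normalization uses the measured sample at 48 h when present, otherwise
#' linear interpolation in time.
#'
#' @param times Hours, strictly increasing, covering 48 h.
#' @param netods netOD values, same length.
#' @return A data.frame with `time_h` and `rate_pct_per_h`; the
#'   normalization is attached as attribute `"netod_48h"`.
#' @export
differential_growth_rate <- function(times, netods) {
  assert_increasing(times, "times")
  if (length(netods) != length(times)) stop_pf("times and netods differ in length")
  if (max(times) < 48) stop_pf("series must reach 48 h for normalization")
  y48 <- if (any(times == 48)) netods[match(48, times)] else
    stats::approx(times, netods, xout = 48)$y
  if (!is.finite(y48) || y48 <= 0) stop_pf("netOD at 48 h must be > 0")
  m <- length(times)
  deriv <- numeric(m)
  deriv[1] <- (netods[2] - netods[1]) / (times[2] - times[1])
  deriv[m] <- (netods[m] - netods[m - 1]) / (times[m] - times[m - 1])
  for (i in seq_len(m - 2) + 1L) {
    h1 <- times[i] - times[i - 1]
    h2 <- times[i + 1] - times[i]
    # Lagrange derivative at the middle node of three
    deriv[i] <- -h2 / (h1 * (h1 + h2)) * netods[i - 1] +
      (h2 - h1) / (h1 * h2) * netods[i] +
      h1 / (h2 * (h1 + h2)) * netods[i + 1]
  }
  out <- data.frame(time_h = times, rate_pct_per_h = 100 * deriv / y48)
  attr(out, "netod_48h") <- y48
  out
}

# analytic growth rate of a fitted model, %/h normalized to netOD(48 h)
model_growth_rate <- function(model, t) {
  y48 <- eval_kinetics(model, 48)
  100 * (model$C1 / model$T1 * exp(-t / model$T1) +
         model$C2 / model$T2 * exp(-t / model$T2)) / y48
}

#' Time at which darkening plateaus
#'
#' The plateau is declared where the differential growth rate falls below a
#' threshold, by convention 0.05 %/h.  For a fitted model the analytic rate
#' is monotone decreasing, so the first crossing is found by root bracketing
#' (`uniroot`); a model already below threshold at t = 0 returns 0.  For a
#' raw series, the first grid time where the numerical rate drops below the
#' threshold and stays there is returned.
#'
#' @param model A fitted kinetics model (list with `netod_inf`, `C1`, `T1`,
#'   `C2`, `T2`).
#' @param threshold Rate threshold in %/h, > 0 (may be `Inf`).
#' @param t_max Search horizon in hours.
#' @return Plateau time in hours.
#' @export
plateau_time <- function(model, threshold = 0.05, t_max = 1e4) {
  if (threshold <= 0) stop_pf("threshold must be > 0")
  f <- function(t) model_growth_rate(model, t) - threshold
  if (!is.finite(threshold) || f(0) <= 0) return(0)
  if (f(t_max) > 0) {
    stop_pf("growth rate never falls below %g %%/h (%.4g %%/h at %g h)",
            threshold, model_growth_rate(model, t_max), t_max)
  }
  stats::uniroot(f, c(0, t_max), tol = 1e-8)$root
}

#' @rdname plateau_time
#' @param times,netods A raw series (as in [differential_growth_rate()]).
#' @export
plateau_time_series <- function(times, netods, threshold = 0.05) {
  if (threshold <= 0) stop_pf("threshold must be > 0")
  if (!is.finite(threshold)) return(0)
  r <- abs(differential_growth_rate(times, netods)$rate_pct_per_h)
  below <- rev(cumprod(rev(r < threshold))) == 1  # below from here onwards
  if (!any(below)) {
    stop_pf("rate never settles below %g %%/h (final rate %.4g %%/h)",
            threshold, r[length(r)])
  }
  times[which(below)[1]]
}

#' Fraction of the final netOD reached by time t
#'
#' @inheritParams eval_kinetics
#' @return `eval_kinetics(model, t) / netod_inf`.
#' @export
fraction_of_final <- function(model, t) {
  if (model$netod_inf == 0) stop_pf("netod_inf must be nonzero")
  eval_kinetics(model, t) / model$netod_inf
}

#' Scan-delay correction factor
#'
#' Films are conventionally read 48 h post-irradiation.  A netOD measured
#' earlier, at `t_scan`, can be projected to the reference time by
#' multiplying with `netOD(t_ref) / netOD(t_scan)` from the fitted kinetics.
#'
#' @inheritParams eval_kinetics
#' @param t_scan Actual scan time in hours, > 0 (or 0 if netOD(0) > 0).
#' @param t_ref Reference scan time in hours, default 48.
#' @return Multiplicative correction factor, >= 1 for `t_scan <= t_ref`.
#' @export
time_correction_factor <- function(model, t_scan, t_ref = 48) {
  denom <- eval_kinetics(model, t_scan)
  if (any(denom <= 0)) stop_pf("netOD at t_scan is not positive; factor undefined")
  eval_kinetics(model, t_ref) / denom
}
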