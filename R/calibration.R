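#' Rational dose-response model evaluation
#'
#' The per-channel calibration model is the rational function
#' `netOD(D) = a * D / (1 + b * D^n)` with `a > 0`, `b >= 0`, `n > 0`:
#' linear at low dose (slope `a`) with a saturating correction controlled by
#' `b` and `n`.  With `b = 0` it degenerates to a straight line through the
#' origin.
#'
#' @param params A list or one-channel model with elements `a`, `b`, `n`, or
#'   a [calibration_model()] (then `channel` selects the channel).
#' @param dose Dose(s) in Gy, >= 0.
#' @param channel Channel name when `params` is a full model.
#' @return netOD value(s).
#' @export
eval_forward <- function(params, dose, channel = NULL) {
  if (any(dose < 0)) stop_pf("dose must be >= 0")
  p <- resolve_channel_params(params, channel)
  rational_response(dose, p$a, p$b, p$n)
}

resolve_channel_params <- function(params, channel) {
  if (inherits(params, "calibration_model")) {
    if (is.null(channel)) stop_pf("`channel` is required with a full calibration model")
    params$channels[[match_channel(channel)]]
  } else if (inherits(params, "calibration_truth")) {
    if (is.null(channel)) stop_pf("`channel` is required with a calibration truth")
    ch <- match_channel(channel)
    list(a = params$a[[ch]], b = params$b[[ch]], n = params$n[[ch]])
  } else {
    params
  }
}

#' Fit the forward rational dose-response for one channel
#'
#' Least-squares fit of `netOD = a*D / (1 + b*D^n)` by damped
#' (Levenberg-Marquardt) iteration with a multi-start strategy: the initial
#' slope `a0` comes from the secant through the two lowest doses, and
#' `(b0, n0)` sweeps the grid `{0.01, 0.1, 0.5} x {0.7, 1.0, 1.5, 2.0}`.
#' The start with the smallest final SSE wins; SSE ties go to the smallest
#' fitted `n`.  A multi-start is needed because `n` varies widely between
#' film batches (roughly 0.66-2.1) and a single start is unreliable.
#'
#' @param doses Doses in Gy (>= 6 distinct values required).
#' @param netods Measured netOD values, same length.
#' @param sigmas Optional netOD uncertainties; when given, the fit is
#'   weighted by `1/sigma^2`.
#' @return A list with `a`, `b`, `n`, `r2`, `rmse`, `dose_range`, and
#'   `rmse_ok` (`TRUE` when RMSE < 1e-3, the usual quality gate for
#'   noise-free calibration data).
#' @export
fit_forward <- function(doses, netods, sigmas = NULL) {
  if (length(doses) != length(netods)) stop_pf("doses and netods differ in length")
  if (length(unique(doses)) < 6L) stop_pf("need >= 6 distinct doses to fit")
  if (any(!is.finite(netods))) stop_pf("netods must be finite")
  ord <- order(doses)
  d <- doses[ord]; y <- netods[ord]
  w <- if (is.null(sigmas)) rep(1, length(d)) else {
    s <- sigmas[ord]
    if (any(s <= 0)) stop_pf("sigmas must be > 0 for weighting")
    1 / s^2
  }
  # secant slope through the mean netOD at the two lowest distinct doses
  a0 <- {
    ud <- sort(unique(d[d > 0]))[1:2]
    m1 <- mean(y[d == ud[1]]); m2 <- mean(y[d == ud[2]])
    max((m2 - m1) / (ud[2] - ud[1]), m1 / ud[1], 1e-6)
  }
  sw <- sqrt(w)
  resid_fn <- function(p) sw * (y - p[1] * d / (1 + p[2] * d^p[3]))
  best <- NULL
  for (b0 in c(0.01, 0.1, 0.5)) for (n0 in c(0.7, 1.0, 1.5, 2.0)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = c(a = a0, b = b0, n = n0),
                         lower = c(1e-12, 0, 1e-6),
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-10, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(resid_fn(fit$par)^2)
    n_hat <- fit$par[["n"]]
    if (is.null(best) || sse < best$sse * (1 - 1e-12) ||
        (abs(sse - best$sse) <= 1e-12 * max(sse, 1e-300) && n_hat < best$n)) {
      best <- list(fit = fit, sse = sse, n = n_hat)
    }
  }
  if (is.null(best)) {
    stop_pf("calibration fit failed to converge from any start; check that netOD increases with dose")
  }
  cf <- best$fit$par
  gq <- goodness(list(a = cf[["a"]], b = cf[["b"]], n = cf[["n"]]), d, y)
  list(a = cf[["a"]], b = cf[["b"]], n = cf[["n"]],
       r2 = gq[["r2"]], rmse = gq[["rmse"]],
       rmse_ok = gq[["rmse"]] < 1e-3,
       dose_range = range(d))
}

#' Fit the empirical inverse dose response
#'
#' The forward rational model has no closed-form inverse; instead the
#' relationship `D = a' * netOD + b' * netOD^n'` is fitted to (netOD, dose)
#' pairs evaluated densely (512 points) from the fitted forward curve over
#' its dose range, with `1/D^2` weights so the relative dose error is
#' minimized across the range.  The maximum round-trip relative error
#' `|inverse(forward(D)) - D| / D` over the range is stored as a diagnostic
#' and a warning is raised if it exceeds 2 %.
#'
#' @param forward One-channel forward fit (list with `a`, `b`, `n`,
#'   `dose_range`).
#' @return A list with `a_inv`, `b_inv`, `n_inv`, `roundtrip_max_relerr`,
#'   `roundtrip_worst_dose`.
#' @export
fit_inverse <- function(forward) {
  rng <- forward$dose_range %||% c(0.25, 20)
  lo <- max(rng[1], 1e-3)
  d <- seq(lo, rng[2], length.out = 512)
  x <- eval_forward(forward, d)
  sw <- 1 / d   # sqrt of 1/d^2 weights: minimize relative dose error
  resid_fn <- function(p) sw * (d - (p[1] * x + p[2] * x^p[3]))
  a0 <- d[1] / x[1]
  best <- NULL
  for (n0 in c(0.7, 1.0, 1.5, 2.0, 3.0)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = c(ai = a0, bi = 0.1, ni = n0),
                         lower = c(0, 0, 1e-6),
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-10, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(resid_fn(fit$par)^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best)) stop_pf("inverse fit failed to converge")
  cf <- best$fit$par
  inv <- list(a_inv = cf[["ai"]], b_inv = cf[["bi"]], n_inv = cf[["ni"]])
  d_back <- inv$a_inv * x + inv$b_inv * x^inv$n_inv
  relerr <- abs(d_back - d) / d
  inv$roundtrip_max_relerr <- max(relerr)
  inv$roundtrip_worst_dose <- d[which.max(relerr)]
  if (inv$roundtrip_max_relerr > 0.02) {
    warning(sprintf("inverse round-trip error %.2f%% at %.2f Gy exceeds 2%%",
                    100 * inv$roundtrip_max_relerr, inv$roundtrip_worst_dose),
            call. = FALSE)
  }
  inv
}

#' Batch calibration model across channels
#'
#' Fits forward and inverse models per channel from a calibration table and
#' assembles a `calibration_model` carrying parameters, diagnostics and
#' batch identity.
#'
#' @param data A data.frame with columns `dose_gy`, `channel`, `netod` and
#'   optionally `sigma` (as produced by [simulate_calibration_dataset()]).
#' @param film_model,batch Labels stored with the model.
#' @param weighted Use `1/sigma^2` weights when sigmas are present.
#' @return An object of class `calibration_model` with one fitted channel
#'   entry per channel present in `data`.
#' @export
fit_calibration <- function(data, film_model = "EBT4", batch = "",
                            weighted = FALSE) {
  need <- c("dose_gy", "channel", "netod")
  if (!all(need %in% names(data))) {
    stop_pf("calibration data needs columns %s", paste(need, collapse = ", "))
  }
  channels <- intersect(CHANNELS, unique(data$channel))
  fits <- lapply(channels, function(ch) {
    sub <- data[data$channel == ch, ]
    sig <- if (weighted && "sigma" %in% names(sub)) sub$sigma else NULL
    fwd <- fit_forward(sub$dose_gy, sub$netod, sig)
    c(fwd, fit_inverse(fwd))
  })
  names(fits) <- channels
  structure(list(film_model = film_model, batch = batch, channels = fits,
                 dose_range = fits[[1]]$dose_range),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model %s batch %s, %g-%g Gy>\n",
              x$film_model, x$batch, x$dose_range[1], x$dose_range[2]))
  for (ch in names(x$channels)) {
    p <- x$channels[[ch]]
    cat(sprintf("  %-5s a=%.4f b=%.4f n=%.4f  R2=%.4f RMSE=%.2e\n",
                ch, p$a, p$b, p$n, p$r2, p$rmse))
  }
  invisible(x)
}

#' Convert measured netOD to dose with uncertainty
#'
#' Applies the fitted empirical inverse `D = a'*netOD + b'*netOD^n'` and,
#' by default, polishes the estimate with a few Newton iterations on the
#' strictly monotone forward model (the empirical three-parameter inverse
#' is accurate only to a few percent at the range extremes; the polish
#' makes `netod_to_dose(eval_forward(D))` the identity to numerical
#' tolerance).  netOD uncertainty propagates to dose at first order,
#' `sigma_D = |dD/dnetOD| * sigma_netOD`, with the derivative taken on the
#' curve actually used (forward-model slope when refining, empirical-fit
#' slope otherwise).
#'
#' @param model A [fit_calibration()] model.
#' @param netod netOD value(s); a slightly negative value within the noise
#'   floor maps to 0 Gy.
#' @param sigma netOD uncertainty (scalar or vector), default 0.
#' @param channel Channel name.
#' @param refine Newton-polish the empirical inverse on the forward model
#'   (default `TRUE`).
#' @return data.frame with `dose_gy`, `sigma_gy` and an `extrapolated` flag
#'   for netODs beyond the calibrated range.
#' @export
netod_to_dose <- function(model, netod, sigma = 0, channel = "red",
                          refine = TRUE) {
  ch <- match_channel(channel)
  p <- model$channels[[ch]]
  if (is.null(p)) stop_pf("model has no channel '%s'", channel)
  sigma <- rep_len(sigma, length(netod))
  if (any(sigma < 0)) stop_pf("sigma must be >= 0")
  if (any(netod < -3 * pmax(sigma, .Machine$double.eps))) {
    stop_pf("netOD below -3 sigma is not a valid measurement")
  }
  x <- pmax(netod, 0)
  top <- eval_forward(p, model$dose_range[2])
  dose <- p$a_inv * x + p$b_inv * x^p$n_inv
  fwd_slope <- function(D) {
    # d/dD of a*D/(1 + b*D^n)
    p$a * (1 + p$b * (1 - p$n) * D^p$n) / (1 + p$b * D^p$n)^2
  }
  if (refine) {
    pos <- x > 0
    if (any(pos)) {
      D <- pmax(dose[pos], 1e-9)
      for (it in 1:50) {
        g <- eval_forward(p, D) - x[pos]
        step <- g / fwd_slope(D)
        step[!is.finite(step)] <- 0
        D <- pmax(D - step, 0)
        if (max(abs(g)) < 1e-12) break
      }
      dose[pos] <- D
    }
    dose[!pos] <- 0
    deriv <- ifelse(x > 0, 1 / fwd_slope(pmax(dose, 1e-9)), 1 / p$a)
  } else {
    deriv <- p$a_inv + ifelse(x > 0, p$b_inv * p$n_inv * x^(p$n_inv - 1),
                              if (p$n_inv >= 1) 0 else Inf)
  }
  data.frame(dose_gy = dose, sigma_gy = abs(deriv) * sigma,
             extrapolated = netod > top | netod < 0)
}

#' Goodness of fit of a calibration model
#'
#' `R^2 = 1 - SSres/SStot` and `RMSE = sqrt(SSres / N)` of the forward model
#' against measured (dose, netOD) pairs.
#'
#' @param params One-channel parameters (list with `a`, `b`, `n`) or a
#'   [calibration_model()] plus `channel`.
#' @param doses,netods Measured pairs (N >= 2).
#' @param channel Channel name when `params` is a full model.
#' @return Named vector `c(r2 = , rmse = )`.
#' @export
goodness <- function(params, doses, netods, channel = NULL) {
  if (length(doses) != length(netods)) stop_pf("doses and netods differ in length")
  if (length(doses) < 2L) stop_pf("need >= 2 points for goodness of fit")
  pred <- eval_forward(params, doses, channel)
  res <- netods - pred
  sstot <- sum((netods - mean(netods))^2)
  c(r2 = 1 - sum(res^2) / sstot, rmse = sqrt(mean(res^2)))
}

#' Write or read a calibration model as JSON
#'
#' @param model A [fit_calibration()] model.
#' @param path File path.
#' @export
write_calibration_json <- function(model, path) {
  x <- list(film_model = model$film_model, batch = model$batch,
            dose_range_gy = model$dose_range,
            channels = lapply(model$channels, function(p)
              p[c("a", "b", "n", "a_inv", "b_inv", "n_inv", "r2", "rmse")]))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  chans <- lapply(x$channels, function(p) {
    p <- as.list(p)
    p$dose_range <- as.numeric(x$dose_range_gy)
    p
  })
  structure(list(film_model = x$film_model, batch = x$batch,
                 channels = chans, dose_range = as.numeric(x$dose_range_gy)),
            class = "calibration_model")
}
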