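# Internal helpers shared across modules.

CHANNELS <- c("red", "green", "blue")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Gauss error function and complement, via the normal CDF.
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
erfc <- function(x) 2 * stats::pnorm(-x * sqrt(2))

stop_pf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_num <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_pf("`%s` must be a single finite number", name)
  }
  if (strict_min && x <= min) stop_pf("`%s` must be > %g", name, min)
  if (!strict_min && x < min) stop_pf("`%s` must be >= %g", name, min)
  invisible(x)
}

assert_increasing <- function(x, name) {
  if (length(x) == 0L) stop_pf("`%s` must be non-empty", name)
  if (any(!is.finite(x))) stop_pf("`%s` must be finite", name)
  if (any(diff(x) <= 0)) stop_pf("`%s` must be strictly increasing", name)
  invisible(x)
}

match_channel <- function(channel) {
  match.arg(tolower(channel), CHANNELS)
}
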