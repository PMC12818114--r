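# Shared fixtures, built in code.

# a frame with identical counts everywhere (per-channel values recycled)
uniform_frame <- function(value, shape = c(16L, 16L), dpi = 300) {
  arr <- array(rep(rep_len(value, 3L), each = prod(shape)), dim = c(shape, 3L))
  scan_frame(arr, dpi = dpi)
}

# the worked kinetics fixture used throughout the kinetics docs/tests
fixture_kinetics <- function() {
  list(netod_inf = 0.4, C1 = 0.05, T1 = 1, C2 = 0.03, T2 = 12)
}

kinetics_fixture_truth <- function() {
  kinetics_truth(netod_inf = 0.4, C1 = 0.05, T1 = 1, C2 = 0.03, T2 = 12)
}

# direct arithmetic for the forward dose-response (independent of eval_forward)
rational_oracle <- function(dose, a, b, n) a * dose / (1 + b * dose^n)

batch_params <- list(
  B1 = list(a = c(red = 0.0740, green = 0.0418, blue = 0.0142),
            b = c(red = 0.0842, green = 0.0258, blue = 0.0004),
            n = c(red = 0.9684, green = 1.0355, blue = 2.1124)),
  B2 = list(a = c(red = 0.1084, green = 0.0532, blue = 0.0205),
            b = c(red = 0.2339, green = 0.0959, blue = 0.0593),
            n = c(red = 0.7978, green = 0.7919, blue = 0.8161)),
  B4 = list(a = c(red = 0.1844, green = 0.0912, blue = 0.0393),
            b = c(red = 0.5289, green = 0.2252, blue = 0.2132),
            n = c(red = 0.7403, green = 0.7597, blue = 0.6624)))
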