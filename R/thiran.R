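#' First-order Thiran fractional-delay coefficients
#'
#' Splits a desired group delay `tau >= 1` (samples) into an integer delay
#' `k = floor(tau)` and the first-order all-pass coefficient
#' `a = (1 - frac(tau)) / (1 + frac(tau))`, so that the realized DC group
#' delay `k + (1 - a) / (1 + a)` equals `tau` exactly. `a` lies in (0, 1];
#' `a = 1` is the pure integer delay.
#'
#' @param tau Desired group delay in samples, `>= 1` (vectorized).
#' @return List with integer vector `k` and numeric vector `a`.
#' @export
thiran_coefficients <- function(tau) {
  if (any(!is.finite(tau)) || any(tau < 1))
    stop("Thiran delays require tau >= 1 sample")
  k <- floor(tau)
  f <- tau - k
  list(k = as.integer(k), a = (1 - f) / (1 + f))
}

#' Group delay realized by (k, a)
#' @param k Integer delay part (samples).
#' @param a All-pass coefficient in (0, 1].
#' @return DC group delay `k + (1 - a)/(1 + a)` in samples.
#' @export
thiran_delay <- function(k, a) k + (1 - a) / (1 + a)

#' Run a first-order Thiran all-pass over a signal
#'
#' Reference (R-level) implementation of the fractional-delay filter used on
#' every voxel-to-voxel connection. The default convention realizes
#' `H(z) = z^-k (a + z^-1) / (1 + a z^-1)` via
#' `y(n) = a * (x(n-k) - y(n-1)) + x(n-k-1)`,
#' whose DC group delay is `k + (1-a)/(1+a)`. `convention = "printed"`
#' selects the same recursion with inputs delayed one further sample
#' (`x(n-k-1)`, `x(n-k-2)`), which realizes a delay of `tau + 1`.
#' State (delay line and previous output) is zero before the first sample.
#'
#' @param x Input signal.
#' @param k Integer delay (samples).
#' @param a All-pass coefficient in (0, 1].
#' @param convention `"group_delay"` (default) or `"printed"`.
#' @return Filtered signal, same length as `x`.
#' @export
allpass_filter <- function(x, k, a, convention = c("group_delay", "printed")) {
  convention <- match.arg(convention)
  if (convention == "printed") k <- k + 1L
  n <- length(x)
  xk  <- function(m) if (m >= 1 && m <= n) x[m] else 0
  y <- numeric(n)
  yprev <- 0
  for (i in seq_len(n)) {
    y[i] <- a * (xk(i - k) - yprev) + xk(i - k - 1)
    yprev <- y[i]
  }
  y
}

#' Measure amplitude ratio and phase delay of a filter on a sinusoid
#'
#' Fits `A * sin(w n + phi)` to the steady-state part of a filtered unit
#' sinusoid by linear regression on `sin`/`cos` carriers; used to verify the
#' all-pass unit-magnitude and group-delay properties.
#'
#' @param y Filter output for input `sin(w * (0:(N-1)))`.
#' @param w Angular frequency (rad/sample).
#' @param discard Initial samples to drop (transient).
#' @return List with `amplitude` and `delay` (samples).
#' @export
sine_fit_delay <- function(y, w, discard = floor(length(y) / 4)) {
  n <- seq_along(y) - 1
  keep <- seq.int(discard + 1L, length(y))
  X <- cbind(sin(w * n[keep]), cos(w * n[keep]))
  cf <- qr.solve(X, y[keep])
  amp <- sqrt(sum(cf^2))
  phi <- atan2(cf[2], cf[1])         # y ~ amp * sin(w n + phi)
  delay <- (-phi / w) %% (2 * pi / w)  # unwrap into [0, one period)
  list(amplitude = amp, delay = delay)
}
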