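#' Phenomenological action-potential template
#'
#' Piecewise-smooth normalized action potential: a tanh depolarization
#' upstroke, a plateau, and an exponential repolarization. The template is
#' zero before `onset_ms` and rises to 1. Its discrete time-derivative, after
#' peak normalization, is the control waveform that drives the propagation
#' model (see [make_control_function()]); the algorithm relies only on that
#' normalization, not on the detailed ionic shape.
#'
#' @param t_ms Time points (ms).
#' @param onset_ms Stimulus onset (ms).
#' @param rise_ms 10-90 upstroke duration (ms).
#' @param plateau_ms Plateau duration at full amplitude (ms).
#' @param repol_ms Repolarization time constant (ms).
#' @return Numeric vector, the template evaluated at `t_ms` (dimensionless,
#'   max 1).
#' @export
ap_template <- function(t_ms, onset_ms = 0, rise_ms = 3,
                        plateau_ms = 200, repol_ms = 100) {
  if (rise_ms <= 0 || plateau_ms < 0 || repol_ms <= 0)
    stop("degenerate action-potential durations")
  t <- t_ms - onset_ms
  # tanh centered mid-upstroke; scaled so the 10-90 width is ~rise_ms
  up <- 0.5 * (1 + tanh(2.2 * (t - rise_ms) / rise_ms))
  t_fall <- 2 * rise_ms + plateau_ms
  down <- ifelse(t > t_fall, exp(-(t - t_fall) / repol_ms), 1)
  out <- up * down
  out[t < 0] <- 0
  out
}

#' Build the control waveform u(n)
#'
#' The control function is the discrete time-derivative of the
#' action-potential template, scaled to a maximum value of 1 A/mm^2 (the
#' model's normalized current-density unit). It is injected into the
#' designated sinoatrial voxel through the control vector and propagated to
#' every other voxel by the all-pass network, so each voxel's current-density
#' magnitude peaks at (up to) the same normalized amplitude.
#'
#' @param n_steps Number of samples Nm.
#' @param fs Sampling rate (Hz).
#' @param onset_ms,rise_ms,plateau_ms,repol_ms Template parameters, see
#'   [ap_template()].
#' @return List with `u` (length Nm waveform, A/mm^2 normalized units), `fs`,
#'   and the template parameters.
#' @export
make_control_function <- function(n_steps, fs, onset_ms = 0, rise_ms = 3,
                                  plateau_ms = 200, repol_ms = 100) {
  if (n_steps < 2) stop("need at least two samples")
  total_ms <- 2 * rise_ms + plateau_ms + repol_ms
  if (onset_ms + total_ms > 1000 * n_steps / fs)
    stop("action-potential template does not fit within the simulated duration")
  t_ms <- (seq_len(n_steps) - 1) / fs * 1000
  ap <- ap_template(t_ms, onset_ms, rise_ms, plateau_ms, repol_ms)
  u <- c(0, diff(ap))
  u[t_ms < onset_ms] <- 0
  u <- u / max(u)
  list(u = u, fs = fs, onset_ms = onset_ms, rise_ms = rise_ms,
       plateau_ms = plateau_ms, repol_ms = repol_ms)
}
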