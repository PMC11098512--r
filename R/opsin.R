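#' Double two-state opsin kinetics
#'
#' Parameters of the gating model that shapes simulated photocurrents: an
#' "O" (opening) gate and an "R" (recovery) gate, each relaxing
#' exponentially toward different endpoints during and after the light
#' pulse. The photocurrent is the product of the two gate occupancies.
#'
#' @param O0,O_inf O-gate value at pulse onset and its on-phase asymptote.
#' @param tau_o O-gate time constant (ms).
#' @param R0,R_inf R-gate value at pulse onset and its on-phase asymptote.
#' @param tau_r R-gate time constant (ms).
#' @param t_on,t_off pulse boundaries (ms), defaults 5 and 10 (a 5 ms pulse
#'   preceded by 5 ms of context).
#' @return object of class `opsin_kinetics`.
#' @export
opsin_kinetics <- function(O0 = 0, O_inf = 0.8, tau_o = 3, R0 = 1,
                           R_inf = 0.5, tau_r = 15, t_on = 5, t_off = 10) {
  stopifnot(tau_o > 0, tau_r > 0, t_on < t_off)
  vals <- c(O0, O_inf, R0, R_inf)
  if (any(vals < 0 | vals > 1)) pd_stop("gate endpoints must lie in [0, 1]")
  structure(list(O0 = O0, O_inf = O_inf, tau_o = tau_o,
                 R0 = R0, R_inf = R_inf, tau_r = tau_r,
                 t_on = t_on, t_off = t_off),
            class = "opsin_kinetics")
}

#' Simulated photocurrent waveform
#'
#' Evaluates the double two-state gating model sample by sample. During the
#' pulse each gate relaxes from its initial value toward its on-asymptote;
#' after the pulse the O gate decays to zero from its value at pulse offset
#' while the R gate recovers toward one. The Heaviside convention is
#' `theta(0) = 1`, so pulse-on intervals are closed on the left, and the
#' waveform is continuous at pulse offset by construction.
#'
#' @param kinetics an [opsin_kinetics()].
#' @param fs sampling rate in Hz.
#' @param n_samples number of samples to evaluate (starting at t = 0).
#' @param normalize if `TRUE`, scale to unit peak (the simulator then
#'   applies per-trial amplitudes in pA); shape is unchanged.
#' @return numeric vector of length `n_samples`.
#' @export
photocurrent_waveform <- function(kinetics, fs = 20000, n_samples,
                                  normalize = FALSE) {
  t <- (seq_len(n_samples) - 1L) / fs * 1000  # ms
  k <- kinetics
  on <- as.numeric(t >= k$t_on & t < k$t_off)   # theta(t-t_on) - theta(t-t_off)
  off <- as.numeric(t >= k$t_off)
  O_on <- on * (k$O_inf - (k$O_inf - k$O0) * exp(-(t - k$t_on) / k$tau_o))
  R_on <- on * (k$R_inf - (k$R_inf - k$R0) * exp(-(t - k$t_on) / k$tau_r))
  O_end <- k$O_inf - (k$O_inf - k$O0) * exp(-(k$t_off - k$t_on) / k$tau_o)
  R_end <- k$R_inf - (k$R_inf - k$R0) * exp(-(k$t_off - k$t_on) / k$tau_r)
  O_off <- off * O_end * exp(-(t - k$t_off) / k$tau_o)
  R_off <- off * (1 - (1 - R_end) * exp(-(t - k$t_off) / k$tau_r))
  I <- (O_on + O_off) * (R_on + R_off)
  if (normalize && max(I) > 0) I <- I / max(I)
  I
}
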