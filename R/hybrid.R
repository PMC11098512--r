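#' Spatially decaying photocurrent contamination field
#'
#' Describes synthetic photocurrent contamination with a spatial footprint:
#' mean evoked amplitude falls off as a 3-D Gaussian of distance from the
#' postsynaptic cell and grows sigmoidally with laser power. Used to
#' contaminate clean (artifact-free) maps for ground-truth validation.
#'
#' @param c_um length-3 postsynaptic cell location (um).
#' @param Sigma 3x3 diagonal spatial covariance (um^2).
#' @param phi0 amplitude scale (pA): the mean amplitude at the cell at high
#'   power.
#' @param phi1 power half-point (mW): power at which the sigmoid reaches
#'   one half.
#' @param sigma_A trial-to-trial amplitude SD (pA).
#' @return object of class `hybrid_field`.
#' @export
hybrid_field <- function(c_um = c(0, 0, 0), Sigma = diag(c(900, 900, 900)),
                         phi0 = 500, phi1 = 40, sigma_A = 25) {
  Sigma <- as.matrix(Sigma)
  if (any(diag(Sigma) <= 0)) pd_stop("Sigma diagonal must be positive")
  structure(list(c_um = as.numeric(c_um), Sigma = Sigma,
                 phi0 = phi0, phi1 = phi1, sigma_A = sigma_A),
            class = "hybrid_field")
}

#' Mean contamination amplitude at a location and power
#'
#' `mu_k = exp(-(x - c)' Sigma^-1 (x - c)) * phi0 * sigmoid(I - phi1)`.
#'
#' @param x_um stimulus location, length-3 vector or n x 3 matrix.
#' @param I_k laser power (vectorized alongside rows of `x_um`).
#' @param field a [hybrid_field()].
#' @return mean amplitude(s) in pA.
#' @export
hybrid_mean_amplitude <- function(x_um, I_k, field) {
  if (is.null(dim(x_um))) x_um <- matrix(x_um, nrow = 1L)
  d <- sweep(x_um, 2L, field$c_um)
  quad <- rowSums((d %*% solve(field$Sigma)) * d)
  drop(exp(-quad) * field$phi0 * plogis(I_k - field$phi1))
}

#' Inject spatial photocurrent contamination into clean traces
#'
#' Adds scaled photocurrent waveforms, with amplitudes drawn from the
#' spatial field at each trial's stimulus location and power, to supplied
#' artifact-free traces (typically a photocurrent-free simulated map).
#' Injection is per snippet, at laser onset.
#'
#' @param raw clean trials x samples matrix in the original inward-negative
#'   polarity.
#' @param metadata a [stimulus_metadata()] with `target_locations_um` set;
#'   for ensemble trials the contamination of all stimulated targets sums.
#' @param field a [hybrid_field()].
#' @param kinetics an [opsin_kinetics()] shaping the injected waveform.
#' @param window a [window_spec()] locating laser onset.
#' @return list `raw` (contaminated traces, original polarity), `A`
#'   (injected per-trial amplitude, pA), `mu` (per-trial mean amplitude).
#' @export
inject_hybrid <- function(raw, metadata, field, kinetics, window) {
  raw <- as.matrix(raw)
  n_trials <- nrow(raw)
  n_samples <- ncol(raw)
  fs <- window$sampling_rate_hz
  locs <- metadata$target_locations_um
  if (is.null(locs)) pd_stop("metadata must carry target locations")
  wf <- photocurrent_waveform(kinetics, fs, n_samples, normalize = TRUE)
  A <- numeric(n_trials)
  mu_out <- numeric(n_trials)
  out <- raw
  for (k in seq_len(n_trials)) {
    tg <- metadata$targets[[k]]
    mu_k <- sum(hybrid_mean_amplitude(locs[tg, , drop = FALSE],
                                      metadata$powers_mW[k], field))
    mu_out[k] <- mu_k
    a <- max(rnorm(1L, mean = mu_k, sd = field$sigma_A), 0)
    if (a > 0) {
      out[k, ] <- out[k, ] - a * wf  # inward-negative polarity
      A[k] <- a
    }
  }
  list(raw = out, A = A, mu = mu_out)
}
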