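# Flip a signed trace matrix into the inward-positive convention.
as_inward_positive <- function(x, polarity = c("inward_positive", "inward_negative")) {
  polarity <- match.arg(polarity)
  x <- as.matrix(x)
  if (polarity == "inward_negative") -x else x
}

#' Mean evoked charge per target and power
#'
#' Charge transfer per trial, averaged over all single-target stimulations
#' of each (target, power) pair. Charges are computed on signed
#' (non-rectified) traces so baseline noise averages to zero rather than
#' biasing every response upward.
#'
#' @param traces trials x samples matrix of demixed traces.
#' @param metadata a [stimulus_metadata()] (single-target trials only).
#' @param window a [window_spec()].
#' @param polarity sign convention of `traces`.
#' @param response_window_samples optional override of the charge window
#'   length (e.g. truncated at the inter-stimulus interval, see
#'   [effective_response_window()]).
#' @return list with `mean_charge` (targets x powers, `NA` where a target
#'   has no trials at that power), `n_trials` (same shape), `powers`,
#'   `charges` (per-trial) and `missing` (targets with no trials at all).
#' @export
per_target_responses <- function(traces, metadata, window,
                                 polarity = c("inward_positive", "inward_negative"),
                                 response_window_samples = NULL) {
  if (!is.null(response_window_samples))
    window$response_window_samples <- as.integer(response_window_samples)
  tr <- as_inward_positive(traces, match.arg(polarity))
  sizes <- vapply(metadata$targets, length, 1L)
  if (any(sizes != 1L))
    pd_stop("per_target_responses expects single-target trials; use the spike-matrix regression for ensembles")
  target <- vapply(metadata$targets, `[[`, 1L, 1L)
  powers <- sort(unique(metadata$powers_mW))
  n_targets <- max(target)
  charges <- charge_transfer(tr, window, window$sampling_rate_hz)
  mean_charge <- matrix(NA_real_, n_targets, length(powers),
                        dimnames = list(NULL, paste0("p", powers)))
  n_trials <- matrix(0L, n_targets, length(powers))
  for (j in seq_along(powers)) {
    sel <- metadata$powers_mW == powers[j]
    agg <- tapply(charges[sel], target[sel], mean)
    ids <- as.integer(names(agg))
    mean_charge[ids, j] <- agg
    cnt <- tapply(charges[sel], target[sel], length)
    n_trials[as.integer(names(cnt)), j] <- as.integer(cnt)
  }
  missing <- which(rowSums(n_trials) == 0L)
  if (length(missing))
    pd_log(1L, "targets with no trials: %s", paste(missing, collapse = ", "))
  list(mean_charge = mean_charge, n_trials = n_trials, powers = powers,
       charges = charges, target = target, missing = missing)
}

#' Response window truncated at the inter-stimulus interval
#'
#' At short ISIs the tail of the standard 35 ms charge window overlaps the
#' next trial's stimulus, whose artifact is deliberately *not* subtracted
#' from the current snippet (the decay constraint confines each fit to its
#' own trial). Detection therefore integrates only up to the next onset.
#' When trial times are unknown the full window is used.
#'
#' @param window a [window_spec()].
#' @param metadata a [stimulus_metadata()] (uses `trial_times_s`).
#' @return integer number of samples.
#' @export
effective_response_window <- function(window, metadata) {
  rw <- window$response_window_samples
  times <- metadata$trial_times_s
  if (!is.null(times) && length(times) > 1L) {
    isi_samples <- floor(min(diff(sort(times))) * window$sampling_rate_hz)
    rw <- min(rw, isi_samples)
  }
  as.integer(rw)
}

# Robust per-sample noise SD from the pre-stimulus context of signed
# inward-positive traces. Only the negative half is used: artifacts, PSC
# tails and any clamping from subtraction are all one-sided positive, so
# negative samples are uncontaminated noise.
estimate_noise_sd <- function(traces, window) {
  if (window$t1 < 2L) pd_stop("no pre-stimulus samples to estimate noise from")
  pre <- as.matrix(traces)[, seq_len(window$t1 - 1L), drop = FALSE]
  neg <- pre[pre < 0]
  if (length(neg) < 20L) return(stats::mad(as.vector(pre), center = 0))
  stats::median(abs(neg)) / 0.6745
}

#' Threshold-based connection detection
#'
#' Simple stand-in for a full statistical connectivity pipeline: a target
#' is called connected when its mean evoked charge at the highest laser
#' power exceeds `k_sigma` times the standard error of the noise-floor
#' charge. For ensemble experiments the per-trial charges are first
#' unmixed into per-target coefficients by nonnegative least squares
#' against the trial-by-target stimulation design.
#'
#' @param traces trials x samples matrix of (demixed) traces.
#' @param metadata a [stimulus_metadata()].
#' @param window a [window_spec()].
#' @param k_sigma detection threshold in noise SD units (default 4).
#' @param noise_sd per-sample noise SD; estimated from the pre-stimulus
#'   context when `NULL`.
#' @param polarity sign convention of `traces`.
#' @param response_window_samples charge integration length; by default the
#'   standard window truncated at the ISI ([effective_response_window()]).
#' @return object of class `connectivity_estimate`: `weights` (mean evoked
#'   charge at max power, pA*ms, for every target), `detected`,
#'   `threshold`, `noise_sd`, `mode`, and the per-target `responses`.
#' @export
detect_connections <- function(traces, metadata, window, k_sigma = 4,
                               noise_sd = NULL,
                               polarity = c("inward_positive", "inward_negative"),
                               response_window_samples = NULL) {
  if (k_sigma <= 0) pd_stop("k_sigma must be > 0")
  polarity <- match.arg(polarity)
  tr <- as_inward_positive(traces, polarity)
  if (is.null(noise_sd)) noise_sd <- estimate_noise_sd(tr, window)
  if (is.null(response_window_samples))
    response_window_samples <- effective_response_window(window, metadata)
  window$response_window_samples <- as.integer(response_window_samples)
  fs <- window$sampling_rate_hz
  # SD of a single-trial charge under pure noise
  sigma_charge <- noise_sd * sqrt(window$response_window_samples) * 1000 / fs
  sizes <- vapply(metadata$targets, length, 1L)
  n_targets <- max(unlist(metadata$targets))
  at_max <- metadata$powers_mW == metadata$max_power_mW

  if (all(sizes == 1L)) {
    resp <- per_target_responses(tr, metadata, window)
    jmax <- which(resp$powers == metadata$max_power_mW)
    weights <- resp$mean_charge[, jmax]
    counts <- resp$n_trials[, jmax]
    # detect on the per-target MEDIAN trial charge: evoked responses recur on
    # nearly every max-power trial while spontaneous PSCs are rare per trial,
    # so the median suppresses their heavy-tailed charge. The reported weight
    # stays the mean charge.
    target_max <- resp$target[at_max]
    med <- rep(NA_real_, n_targets)
    agg <- tapply(resp$charges[at_max], target_max, stats::median)
    med[as.integer(names(agg))] <- agg
    # empirical null for the charge background: spontaneous activity and
    # prior-trial tails skew single-trial charges beyond electrical noise,
    # so the null center/scale come from the max-power charges themselves
    # (median/MAD are robust to the ~10-25% of trials with true responses),
    # floored at the white-noise propagation
    ch_max <- resp$charges[at_max]
    null_center <- stats::median(ch_max)
    sigma_charge <- max(sigma_charge, stats::mad(ch_max))
    detect_stat <- med - null_center
    stat_se_factor <- 1.2533  # SE of a median relative to the mean, Gaussian
    mode <- "single_target"
    responses <- resp
  } else {
    charges <- charge_transfer(tr[at_max, , drop = FALSE], window, fs)
    design <- matrix(0, sum(at_max), n_targets)
    kk <- which(at_max)
    for (i in seq_along(kk)) design[i, metadata$targets[[kk[i]]]] <- 1
    weights <- nnls_solve(design, charges)
    counts <- colSums(design)
    detect_stat <- weights
    stat_se_factor <- 1
    mode <- "ensemble"
    responses <- list(charges = charges, design = design)
  }
  threshold <- k_sigma * stat_se_factor * sigma_charge / sqrt(pmax(counts, 1L))
  detected <- !is.na(detect_stat) & counts > 0 & detect_stat > threshold
  structure(list(weights = weights, detected = detected,
                 threshold = threshold, noise_sd = noise_sd,
                 k_sigma = k_sigma, mode = mode, responses = responses),
            class = "connectivity_estimate")
}

#' @export
print.connectivity_estimate <- function(x, ...) {
  cat(sprintf("<connectivity_estimate> %d targets, %d detected (%s mode, k_sigma = %g)\n",
              length(x$weights), sum(x$detected, na.rm = TRUE), x$mode, x$k_sigma))
  invisible(x)
}

#' Presynaptic success matrix surrogate
#'
#' Builds the cells x trials success matrix consumed by
#' [connection_waveforms()]: entry 1 when the cell was stimulated on that
#' trial and the trial's evoked charge clears the detection floor, else 0.
#' A thresholding stand-in for a posterior spike-probability matrix.
#'
#' @param metadata a [stimulus_metadata()].
#' @param charges per-trial evoked charge (pA*ms).
#' @param floor charge floor above which a trial counts as a success.
#' @param n_targets number of cells (rows).
#' @return cells x trials 0/1 matrix.
#' @export
spike_matrix_surrogate <- function(metadata, charges, floor, n_targets) {
  n_trials <- length(metadata$targets)
  L <- matrix(0, n_targets, n_trials)
  for (k in seq_len(n_trials))
    if (charges[k] > floor) L[metadata$targets[[k]], k] <- 1
  L
}

#' Nonnegative ridge regression of connection waveforms
#'
#' Recovers a per-cell PSC waveform from trial traces and a presynaptic
#' success matrix `Lambda` by solving, columnwise over time samples,
#' \deqn{\hat W = \arg\min_{W \ge 0} \|C - \Lambda' W\|_F^2 +
#'       \lambda \|W\|_F^2.}
#' Use trials at the highest laser power only, where successes are most
#' reliable.
#'
#' @param C trials x samples matrix of demixed traces.
#' @param Lambda cells x trials success/probability matrix.
#' @param lambda_ridge ridge penalty (default 1).
#' @return cells x samples nonnegative waveform matrix.
#' @export
connection_waveforms <- function(C, Lambda, lambda_ridge = 1) {
  C <- as.matrix(C)
  Lambda <- as.matrix(Lambda)
  if (ncol(Lambda) != nrow(C))
    pd_stop("Lambda has %d trials but C has %d", ncol(Lambda), nrow(C))
  dead <- rowSums(abs(Lambda)) == 0
  if (any(dead))
    warning(sprintf("cells with all-zero success rows returned as zeros: %s",
                    paste(which(dead), collapse = ", ")))
  A <- t(Lambda[!dead, , drop = FALSE])
  W <- matrix(0, nrow(Lambda), ncol(C))
  if (ncol(A) > 0) {
    Aaug <- rbind(A, sqrt(lambda_ridge) * diag(ncol(A)))
    pad <- numeric(ncol(A))
    W[!dead, ] <- vapply(seq_len(ncol(C)),
                         function(t) nnls_solve(Aaug, c(C[, t], pad)),
                         numeric(ncol(A)))
  }
  W
}

#' Pick representative trials for inspection
#'
#' Two index lists used when plotting model behaviour: the trials with the
#' largest fitted artifact during stimulation, and the trials with the
#' largest demixed charge inside the monosynaptic latency window
#' (3--12 ms after laser onset), i.e. the strongest putative evoked PSCs.
#'
#' @param estimate a `photocurrent_estimate` or `demix_fit` (anything with
#'   an `artifact` matrix).
#' @param demixed trials x samples demixed traces (rectified domain).
#' @param window a [window_spec()].
#' @param n trials per category (default 15); truncated with a warning if
#'   larger than the number of trials.
#' @param latency_window_ms monosynaptic latency window, default `c(3, 12)`.
#' @return list with integer vectors `photocurrent` and `synaptic`.
#' @export
select_representative_traces <- function(estimate, demixed, window, n = 15L,
                                         latency_window_ms = c(3, 12)) {
  artifact <- estimate$artifact
  N <- nrow(artifact)
  if (n > N) {
    warning(sprintf("n = %d exceeds trial count %d; truncating", n, N))
    n <- N
  }
  fs <- window$sampling_rate_hz
  stim_idx <- window$t1:(window$t1 + window$stim_duration_samples - 1L)
  photo_score <- rowSums(artifact[, stim_idx, drop = FALSE])
  lat_idx <- (window$t1 + ms_to_samples(latency_window_ms[1], fs)):
    min(window$t1 + ms_to_samples(latency_window_ms[2], fs), ncol(artifact))
  syn_score <- rowSums(as.matrix(demixed)[, lat_idx, drop = FALSE])
  list(photocurrent = utils::head(order(photo_score, decreasing = TRUE), n),
       synaptic = utils::head(order(syn_score, decreasing = TRUE), n))
}

#' Score estimated connectivity against simulated ground truth
#'
#' Computes the coefficient of determination between true and estimated
#' weights over all targets, plus false-positive/negative counts.
#' Estimated weights are in charge units (pA*ms) while simulator weights
#' are peak amplitudes (pA); by default a single least-squares gain maps
#' the estimates onto the true scale before computing R-squared
#' (`gain_correct = FALSE` skips this and compares raw values).
#' Undetected targets contribute an estimated weight of zero.
#'
#' @param truth ground-truth list with `connected` and `weights` (as
#'   returned in `simulate_mapping_experiment()$truth`).
#' @param estimate a `connectivity_estimate`, or a list with `weights` and
#'   `detected`.
#' @param gain_correct fit a single positive gain before scoring.
#' @return object of class `eval_report`: `r_squared`, `gain`,
#'   `true_positives`, `false_positives`, `false_negatives`, `n_targets`,
#'   and the per-target table `targets`.
#' @export
evaluate_connectivity <- function(truth, estimate, gain_correct = TRUE) {
  true_w <- truth$weights
  est_w <- ifelse(estimate$detected & !is.na(estimate$weights),
                  estimate$weights, 0)
  if (length(est_w) != length(true_w))
    pd_stop("target sets differ: %d true vs %d estimated",
            length(true_w), length(est_w))
  g <- 1
  if (gain_correct && sum(est_w^2) > 0)
    g <- sum(true_w * est_w) / sum(est_w^2)
  fitted <- g * est_w
  ss_tot <- sum((true_w - mean(true_w))^2)
  r2 <- if (ss_tot == 0) NA_real_ else 1 - sum((true_w - fitted)^2) / ss_tot
  if (is.na(r2)) pd_log(1L, "constant true weights: R^2 undefined")
  connected <- as.logical(truth$connected)
  det <- as.logical(estimate$detected)
  structure(list(
    r_squared = r2, gain = g,
    true_positives = sum(det & connected),
    false_positives = sum(det & !connected),
    false_negatives = sum(!det & connected),
    n_targets = length(true_w),
    targets = data.frame(true_weight = true_w, estimated_weight = est_w,
                         fitted_weight = fitted, detected = det,
                         connected = connected)),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> R^2 = %.3f (gain %.3g); TP %d, FP %d, FN %d of %d targets\n",
              x$r_squared, x$gain, x$true_positives, x$false_positives,
              x$false_negatives, x$n_targets))
  invisible(x)
}
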