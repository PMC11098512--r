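#' Trial-aligned, rectified current traces
#'
#' Container for the N x T matrix of trial-aligned voltage-clamp snippets on
#' which all demixing operates. Values are stored rectified: inward current is
#' positive and anything below zero has been clipped, so the matrix is
#' elementwise nonnegative. The original recording sign convention is kept so
#' traces can be returned to the caller in their native polarity.
#'
#' @param values N x T numeric matrix of nonnegative currents (pA,
#'   inward-positive after rectification).
#' @param sampling_rate_hz sampling rate (default 20000).
#' @param stim_onset_sample 1-based index of the first laser-on sample.
#' @param stim_duration_samples number of laser-on samples.
#' @param input_polarity `"inward_negative"` (typical voltage clamp at
#'   -70 mV) or `"inward_positive"`; records the sign convention of the raw
#'   input, it is never inferred.
#' @return An object of class `trace_matrix`.
#' @seealso [rectify_traces()] which constructs this from raw signed traces.
#' @export
trace_matrix <- function(values, sampling_rate_hz = 20000,
                         stim_onset_sample, stim_duration_samples,
                         input_polarity = c("inward_negative", "inward_positive")) {
  input_polarity <- match.arg(input_polarity)
  values <- as.matrix(values)
  if (nrow(values) < 1L) pd_stop("trace_matrix needs at least one trial")
  if (any(!is.finite(values))) {
    bad <- unique(which(!is.finite(values), arr.ind = TRUE)[, 1L])
    pd_stop("non-finite values in trials: %s", paste(bad, collapse = ", "))
  }
  if (any(values < 0)) pd_stop("trace_matrix values must be rectified (>= 0)")
  stim_onset_sample <- as.integer(stim_onset_sample)
  stim_duration_samples <- as.integer(stim_duration_samples)
  if (ncol(values) < stim_onset_sample + stim_duration_samples)
    pd_stop("snippet too short: T = %d < stim onset %d + duration %d",
            ncol(values), stim_onset_sample, stim_duration_samples)
  structure(list(
    values = values,
    sampling_rate_hz = sampling_rate_hz,
    stim_onset_sample = stim_onset_sample,
    stim_duration_samples = stim_duration_samples,
    input_polarity = input_polarity
  ), class = "trace_matrix")
}

#' @export
print.trace_matrix <- function(x, ...) {
  cat(sprintf(
    "<trace_matrix> %d trials x %d samples @ %g kHz; stim on at sample %d for %d samples; input polarity %s\n",
    nrow(x$values), ncol(x$values), x$sampling_rate_hz / 1000,
    x$stim_onset_sample, x$stim_duration_samples, x$input_polarity))
  invisible(x)
}

#' @export
dim.trace_matrix <- function(x) dim(x$values)

#' Rectify raw signed traces into a [trace_matrix()]
#'
#' Flips the sign if needed so inward current is positive, then clips at zero:
#' sub-zero deflections after the flip are attributed to noise. The declared
#' polarity is stored so demixed traces can later be handed back in the
#' caller's convention.
#'
#' @param raw N x T signed current matrix (or a single trace as a vector).
#' @param polarity sign convention of `raw`; required, never auto-detected
#'   (detection is unreliable on artifact-dominated recordings).
#' @param sampling_rate_hz,stim_onset_sample,stim_duration_samples see
#'   [trace_matrix()].
#' @param units input units, converted to pA internally.
#' @return A [trace_matrix()].
#' @examples
#' y <- rectify_traces(rbind(c(-1, 2, -3)), "inward_negative",
#'                     stim_onset_sample = 1, stim_duration_samples = 2)
#' y$values  # 1 0 3
#' @export
rectify_traces <- function(raw, polarity = c("inward_negative", "inward_positive"),
                           sampling_rate_hz = 20000,
                           stim_onset_sample = 1L,
                           stim_duration_samples = 1L,
                           units = "pA") {
  polarity <- match.arg(polarity)
  if (is.null(dim(raw))) raw <- matrix(raw, nrow = 1L)
  raw <- to_pA(as.matrix(raw), units)
  if (any(!is.finite(raw))) {
    bad <- unique(which(!is.finite(raw), arr.ind = TRUE)[, 1L])
    pd_stop("non-finite samples in trials: %s", paste(bad, collapse = ", "))
  }
  flipped <- if (polarity == "inward_negative") -raw else raw
  trace_matrix(pmax(flipped, 0), sampling_rate_hz,
               stim_onset_sample, stim_duration_samples, polarity)
}

#' Timing landmarks of a trial snippet
#'
#' Holds the sample indices that structure every snippet: `t1`, laser onset;
#' `t2`, end of the artifact integration window (the short stretch used to
#' learn per-trial artifact weights); `t3`, the sample from which the
#' current-trial waveform is forced to decay (guards against absorbing the
#' following trial); and the length of the charge-transfer response window.
#' All indices are 1-based and `t1 <= t2 < t3`.
#'
#' @param t1 laser onset sample (1-based).
#' @param t2 last sample (inclusive) of the integration window. Default:
#'   `t1 - 1 + min(stim_duration, 5 ms)` worth of samples.
#' @param t3 first sample of the enforced decay, default 10 ms after stimulus
#'   offset.
#' @param stim_duration_samples laser-on duration in samples.
#' @param sampling_rate_hz sampling rate, used for ms defaults.
#' @param response_window_ms charge-transfer window length (default 35 ms).
#' @param n_samples snippet length T (used for validation if supplied).
#' @return object of class `window_spec` with integer fields `t1`, `t2`,
#'   `t3`, `response_window_samples`.
#' @export
window_spec <- function(t1, stim_duration_samples, sampling_rate_hz = 20000,
                        t2 = NULL, t3 = NULL,
                        response_window_ms = 35, n_samples = NULL) {
  t1 <- as.integer(t1)
  stim_duration_samples <- as.integer(stim_duration_samples)
  if (is.null(t2)) {
    win <- min(stim_duration_samples, ms_to_samples(5, sampling_rate_hz))
    t2 <- t1 - 1L + as.integer(win)
  }
  t2 <- as.integer(t2)
  if (is.null(t3)) {
    t3 <- t1 + stim_duration_samples + ms_to_samples(10, sampling_rate_hz)
  }
  t3 <- as.integer(t3)
  if (!(t1 >= 1L && t1 <= t2 && t2 < t3))
    pd_stop("window ordering violated: need 1 <= t1 <= t2 < t3 (got %d, %d, %d)",
            t1, t2, t3)
  rw <- ms_to_samples(response_window_ms, sampling_rate_hz)
  if (!is.null(n_samples) && t2 > n_samples)
    pd_stop("integration window end t2 = %d exceeds snippet length %d", t2, n_samples)
  structure(list(t1 = t1, t2 = t2, t3 = t3,
                 stim_duration_samples = stim_duration_samples,
                 sampling_rate_hz = sampling_rate_hz,
                 response_window_samples = as.integer(rw)),
            class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window_spec> t1=%d t2=%d t3=%d (fs %g Hz, response window %d samples)\n",
              x$t1, x$t2, x$t3, x$sampling_rate_hz, x$response_window_samples))
  invisible(x)
}

#' Charge transfer over the response window
#'
#' Integral of the current over a fixed window starting at laser onset; the
#' scalar per-trial response used for mapping. For a trace in pA sampled at
#' `fs` Hz this is `sum(samples) * 1000 / fs`, in pA*ms.
#'
#' @param trace numeric vector (one trial), or a matrix with trials in rows.
#' @param window a [window_spec()].
#' @param sampling_rate_hz sampling rate of `trace`.
#' @return scalar (or vector, one per row) charge in pA*ms.
#' @export
charge_transfer <- function(trace, window, sampling_rate_hz = window$sampling_rate_hz) {
  if (is.null(dim(trace))) trace <- matrix(trace, nrow = 1L)
  idx_end <- window$t1 + window$response_window_samples - 1L
  if (idx_end > ncol(trace))
    pd_stop("response window [%d, %d] overruns trace length %d",
            window$t1, idx_end, ncol(trace))
  s <- rowSums(trace[, window$t1:idx_end, drop = FALSE])
  out <- s * 1000 / sampling_rate_hz
  if (length(out) == 1L) out[[1L]] else out
}

#' Per-trial signal sum during stimulation
#'
#' The "energy" used to order trials before batching: the plain sum of
#' rectified samples while the laser is on. Monotone in artifact amplitude,
#' so sorting by it groups trials with similar artifact size (and kinetics,
#' since kinetics co-vary with power).
#'
#' @param Y a [trace_matrix()] or nonnegative matrix.
#' @param window a [window_spec()].
#' @return numeric vector of length N.
#' @export
stim_energy <- function(Y, window) {
  vals <- if (inherits(Y, "trace_matrix")) Y$values else as.matrix(Y)
  idx_end <- window$t1 + window$stim_duration_samples - 1L
  if (idx_end > ncol(vals))
    pd_stop("stimulus window [%d, %d] overruns trace length %d",
            window$t1, idx_end, ncol(vals))
  rowSums(vals[, window$t1:idx_end, drop = FALSE])
}

#' Partition trials into energy-sorted batches
#'
#' Trials are sorted by descending stimulus-window energy and cut into
#' consecutive batches of `batch_size`. A trailing remainder smaller than
#' `batch_size / 2` is merged into the previous batch: very small batches are
#' prone to over-subtracting PSCs, so they are avoided.
#'
#' @param energies numeric vector from [stim_energy()].
#' @param batch_size target batch size (default 200).
#' @return object of class `batch_partition` with fields `assignment`
#'   (batch id per trial, original order), `order` (permutation sorting trials
#'   by descending energy) and `sizes`.
#' @export
make_batches <- function(energies, batch_size = 200L) {
  batch_size <- as.integer(batch_size)
  if (batch_size < 1L) pd_stop("batch_size must be >= 1")
  n <- length(energies)
  if (n == 0L) {
    return(structure(list(assignment = integer(0), order = integer(0),
                          sizes = integer(0), batch_size = batch_size),
                     class = "batch_partition"))
  }
  ord <- order(energies, decreasing = TRUE)
  n_full <- n %/% batch_size
  rem <- n %% batch_size
  if (n_full == 0L) {
    sizes <- n
  } else if (rem == 0L) {
    sizes <- rep(batch_size, n_full)
  } else if (rem < batch_size / 2) {
    sizes <- rep(batch_size, n_full)
    sizes[n_full] <- sizes[n_full] + rem
  } else {
    sizes <- c(rep(batch_size, n_full), rem)
  }
  assignment <- integer(n)
  assignment[ord] <- rep(seq_along(sizes), times = sizes)
  structure(list(assignment = assignment, order = ord,
                 sizes = as.integer(sizes), batch_size = batch_size),
            class = "batch_partition")
}

#' @export
print.batch_partition <- function(x, ...) {
  cat(sprintf("<batch_partition> %d trials in %d batches (sizes: %s)\n",
              length(x$assignment), length(x$sizes),
              paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Per-trial stimulus metadata
#'
#' Laser powers and target bookkeeping for each trial. Ensemble trials list
#' several targets; single-target trials list one.
#'
#' @param powers_mW length-N vector of per-trial laser powers.
#' @param max_power_mW maximum power used in the experiment.
#' @param targets list of integer vectors (targets stimulated on each trial),
#'   or an integer vector for purely single-target experiments.
#' @param target_locations_um optional targets x 3 matrix of locations.
#' @param trial_times_s optional absolute trial onset times.
#' @return object of class `stimulus_metadata`.
#' @export
stimulus_metadata <- function(powers_mW, max_power_mW = max(powers_mW),
                              targets, target_locations_um = NULL,
                              trial_times_s = NULL) {
  if (!is.list(targets)) targets <- as.list(as.integer(targets))
  if (length(targets) != length(powers_mW))
    pd_stop("targets (%d) and powers (%d) disagree in length",
            length(targets), length(powers_mW))
  if (any(powers_mW < 0) || any(powers_mW > max_power_mW))
    pd_stop("powers must lie in [0, max_power_mW]")
  if (any(vapply(targets, length, 1L) < 1L))
    pd_stop("every trial must reference at least one target")
  structure(list(powers_mW = as.numeric(powers_mW),
                 max_power_mW = as.numeric(max_power_mW),
                 targets = lapply(targets, as.integer),
                 target_locations_um = target_locations_um,
                 trial_times_s = trial_times_s),
            class = "stimulus_metadata")
}
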