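#' Population-level photocurrent parameters
#'
#' Governs which stimulation targets evoke a direct photocurrent in the
#' patched cell and how large it is. A target carries a photocurrent with
#' probability `p`; its mean amplitude at maximum laser power is
#' gamma-distributed. Defaults give a mean artifact of 500 pA
#' (shape 2, scale 250), inside the 0.3--0.8 nA range typical of somatic
#' opsin excitation, with trial-to-trial jitter of 10% of the mean.
#'
#' @param p photocurrent fraction in `[0, 1]`.
#' @param k_photo,theta_photo gamma shape and scale (pA) of the mean
#'   amplitude at maximum power.
#' @param sigma_A trial-to-trial amplitude SD (pA); `NULL` = 10% of each
#'   target's mean.
#' @param kinetics_ranges uniform sampling ranges for the per-experiment
#'   opsin gating parameters, spanning fast to slow decay kinetics.
#' @return object of class `photocurrent_population`.
#' @export
photocurrent_population <- function(p = 0.1, k_photo = 2, theta_photo = 250,
                                    sigma_A = NULL,
                                    kinetics_ranges = list(
                                      tau_o = c(1, 5), tau_r = c(5, 40),
                                      O_inf = c(0.6, 1), R_inf = c(0.3, 1))) {
  stopifnot(p >= 0, p <= 1, k_photo >= 0, theta_photo >= 0)
  structure(list(p = p, k_photo = k_photo, theta_photo = theta_photo,
                 sigma_A = sigma_A, kinetics_ranges = kinetics_ranges),
            class = "photocurrent_population")
}

#' Sample per-target photocurrent traits and the cell's waveform kinetics
#'
#' Draws, for each of `n_cells` targets, a Bernoulli photocurrent flag and
#' (where flagged) a gamma mean amplitude, plus one opsin-kinetics draw for
#' the simulated postsynaptic cell: the artifact arises in the single
#' patched cell, so all targets share one waveform per experiment.
#'
#' @param n_cells number of stimulation targets.
#' @param params a [photocurrent_population()].
#' @param t_on,t_off pulse boundaries (ms) for the kinetics draw.
#' @return list with `q_flags`, `mu` (pA at max power) and `kinetics`.
#'   Uses the current RNG state; seed upstream for reproducibility.
#' @export
sample_photocurrent_traits <- function(n_cells, params = photocurrent_population(),
                                       t_on = 5, t_off = 10) {
  q <- rbinom(n_cells, 1L, params$p)
  mu <- numeric(n_cells)
  n_on <- sum(q)
  if (n_on > 0)
    mu[q == 1L] <- rgamma(n_on, shape = params$k_photo, scale = params$theta_photo)
  r <- params$kinetics_ranges
  kin <- opsin_kinetics(
    O0 = 0, O_inf = runif(1, r$O_inf[1], r$O_inf[2]),
    tau_o = runif(1, r$tau_o[1], r$tau_o[2]),
    R0 = 1, R_inf = runif(1, r$R_inf[1], r$R_inf[2]),
    tau_r = runif(1, r$tau_r[1], r$tau_r[2]),
    t_on = t_on, t_off = t_off)
  list(q_flags = q, mu = mu, kinetics = kin)
}

#' Per-trial photocurrent amplitude
#'
#' Scales a target's mean amplitude by relative laser power and adds
#' Gaussian trial noise, clipping at zero (sub-zero draws carry no physical
#' meaning).
#'
#' @param mu mean amplitude at maximum power (pA); vectorized.
#' @param I_k,I_max trial and maximum laser power.
#' @param sigma_A trial SD (pA); `NULL` = 10% of `mu`.
#' @return nonnegative amplitude(s) `A_k`.
#' @export
trial_amplitude <- function(mu, I_k, I_max, sigma_A = NULL) {
  if (I_max <= 0) pd_stop("I_max must be > 0")
  if (is.null(sigma_A)) sigma_A <- 0.1 * mu
  n <- max(length(mu), length(I_k))
  pmax(rnorm(n, mean = mu * I_k / I_max, sd = sigma_A), 0)
}

#' PSC generative parameters
#'
#' @param weight_shape,weight_scale gamma parameters of connected-cell
#'   synaptic weights (peak amplitude, pA).
#' @param min_latency_ms minimum monosynaptic latency (default 3 ms).
#' @param latency_jitter_ms mean additional latency at maximum power
#'   (default 4 ms, placing typical onsets 5--15 ms after the stimulus:
#'   evoked spike latency plus synaptic delay, with only the early tail of
#'   the distribution reaching into the laser-on window). The mean scales
#'   as `I_max / I`, so latency shrinks with power while amplitude does
#'   not. Latencies are gamma-distributed (shape 2) above the minimum.
#' @param tau_rise_range,tau_decay_range uniform ranges (ms) for the
#'   difference-of-exponentials kernel time constants.
#' @param success_prob_max probability a stimulus at maximum power evokes a
#'   spike/PSC; scales linearly with relative power.
#' @param spont_rate_hz spontaneous PSC rate over the whole recording.
#' @return object of class `psc_params`.
#' @export
psc_params <- function(weight_shape = 2, weight_scale = 25,
                       min_latency_ms = 3, latency_jitter_ms = 4,
                       tau_rise_range = c(0.5, 2), tau_decay_range = c(5, 15),
                       success_prob_max = 0.95, spont_rate_hz = 2) {
  stopifnot(min_latency_ms >= 0, spont_rate_hz >= 0,
            success_prob_max >= 0, success_prob_max <= 1)
  structure(list(weight_shape = weight_shape, weight_scale = weight_scale,
                 min_latency_ms = min_latency_ms,
                 latency_jitter_ms = latency_jitter_ms,
                 tau_rise_range = tau_rise_range,
                 tau_decay_range = tau_decay_range,
                 success_prob_max = success_prob_max,
                 spont_rate_hz = spont_rate_hz),
            class = "psc_params")
}

#' Difference-of-exponentials PSC kernel
#'
#' Unit-peak kernel `exp(-t/tau_decay) - exp(-t/tau_rise)`, zero for
#' `t < 0`. Peaks at `tau_rise * tau_decay / (tau_decay - tau_rise) *
#' log(tau_decay / tau_rise)` ms after onset.
#'
#' @param t_ms time from onset (ms), vectorized.
#' @param tau_rise,tau_decay time constants (ms), `tau_decay > tau_rise`.
#' @return kernel values, unit peak.
#' @export
psc_kernel <- function(t_ms, tau_rise = 1, tau_decay = 10) {
  stopifnot(tau_decay > tau_rise, tau_rise > 0)
  raw <- ifelse(t_ms >= 0, exp(-t_ms / tau_decay) - exp(-t_ms / tau_rise), 0)
  t_peak <- tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
  peak <- exp(-t_peak / tau_decay) - exp(-t_peak / tau_rise)
  raw / peak
}

# Latency draw: minimum plus a gamma-distributed excess (shape 2) whose mean
# shrinks with power (mean = jitter * I_max / I at trial power I).
.psc_latency <- function(n, psc, I, I_max) {
  psc$min_latency_ms +
    rgamma(n, shape = 2, scale = psc$latency_jitter_ms * I_max / (2 * I))
}

#' Simulate evoked and spontaneous PSC trains for a trial block
#'
#' Renders, per trial, the PSC contribution of the stimulated targets (a
#' Bernoulli success with power-scaled probability; on success one
#' difference-of-exponentials event at the power-dependent latency) plus
#' spontaneous events as a Poisson process over the snippet. Each connected
#' target has a canonical kernel; amplitudes equal the target's weight.
#'
#' @param connected logical/0-1 vector per target.
#' @param weights per-target synaptic weight (peak pA).
#' @param powers per-trial laser power.
#' @param targets list of stimulated target ids per trial.
#' @param psc a [psc_params()].
#' @param n_samples snippet length; `t_on_ms` laser onset within snippet.
#' @param fs sampling rate (Hz).
#' @param I_max maximum power.
#' @param taus optional 2-column matrix of per-target (rise, decay) ms;
#'   drawn from the configured ranges when absent.
#' @return list `traces` (trials x samples, inward-positive pA) and
#'   `events` (data.frame: trial, target (NA = spontaneous), time_ms from
#'   snippet start, amplitude).
#' @export
simulate_psc_train <- function(connected, weights, powers, targets,
                               psc = psc_params(), n_samples, t_on_ms = 5,
                               fs = 20000, I_max = max(powers), taus = NULL) {
  n_targets <- length(connected)
  n_trials <- length(powers)
  if (!is.list(targets)) targets <- as.list(as.integer(targets))
  if (is.null(taus)) {
    taus <- cbind(runif(n_targets, psc$tau_rise_range[1], psc$tau_rise_range[2]),
                  runif(n_targets, psc$tau_decay_range[1], psc$tau_decay_range[2]))
  }
  t_ms <- (seq_len(n_samples) - 1L) / fs * 1000
  traces <- matrix(0, n_trials, n_samples)
  ev <- list()
  snip_ms <- n_samples / fs * 1000
  for (k in seq_len(n_trials)) {
    for (tg in targets[[k]]) {
      if (!connected[tg]) next
      p_succ <- psc$success_prob_max * powers[k] / I_max
      if (rbinom(1L, 1L, min(p_succ, 1)) == 1L) {
        lat <- .psc_latency(1L, psc, powers[k], I_max)
        onset <- t_on_ms + lat
        traces[k, ] <- traces[k, ] +
          weights[tg] * psc_kernel(t_ms - onset, taus[tg, 1], taus[tg, 2])
        ev[[length(ev) + 1L]] <- data.frame(
          trial = k, target = tg, time_ms = onset, amplitude = weights[tg])
      }
    }
    n_spont <- rpois(1L, psc$spont_rate_hz * snip_ms / 1000)
    if (n_spont > 0) {
      for (j in seq_len(n_spont)) {
        onset <- runif(1, 0, snip_ms)
        amp <- rgamma(1, shape = psc$weight_shape, scale = psc$weight_scale)
        tr <- runif(1, psc$tau_rise_range[1], psc$tau_rise_range[2])
        td <- runif(1, psc$tau_decay_range[1], psc$tau_decay_range[2])
        traces[k, ] <- traces[k, ] + amp * psc_kernel(t_ms - onset, tr, td)
        ev[[length(ev) + 1L]] <- data.frame(
          trial = k, target = NA_integer_, time_ms = onset, amplitude = amp)
      }
    }
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(trial = integer(0), target = integer(0),
               time_ms = numeric(0), amplitude = numeric(0))
  list(traces = traces, events = events, taus = taus)
}

#' Simulate a complete optogenetic mapping experiment
#'
#' Builds a continuous voltage-clamp recording by summing, at each
#' scheduled trial: the scaled photocurrent waveform of the patched cell
#' (amplitudes from the population model, summed over stimulated targets
#' for ensembles), evoked PSC trains with power-dependent latency,
#' spontaneous PSCs, and white Gaussian noise. The recording is then cut
#' into overlapping snippets aligned `context_ms` before each stimulus, so
#' at short inter-stimulus intervals each snippet carries the decaying tail
#' of the previous trial and the onset of the next -- the regime the
#' baseline term and the post-`t3` decay constraint exist for.
#'
#' @param n_targets number of presynaptic candidate targets (default 100).
#' @param connection_prob probability a target is synaptically connected
#'   (default 0.1).
#' @param photo a [photocurrent_population()].
#' @param psc a [psc_params()].
#' @param powers_mW laser powers cycled over (default 3 powers).
#' @param n_reps repetitions per (target/ensemble, power) (default 5; kept
#'   modest so a full experiment fits desk-scale runtimes).
#' @param ensemble_size targets stimulated simultaneously (1 =
#'   single-target mapping).
#' @param isi_ms inter-stimulus interval (default 30 ms).
#' @param snippet_ms,context_ms,pulse_ms snippet length, pre-stimulus
#'   context and pulse duration (defaults 45 / 5 / 5 ms).
#' @param fs sampling rate (default 20 kHz).
#' @param noise_sd additive white noise SD (pA, default 5).
#' @param seed optional integer; when given, `set.seed(seed)` is called so
#'   the whole experiment is reproducible from `(seed, config)`.
#' @return list with `raw` (trials x samples, original inward-negative
#'   polarity, pA), `metadata` (a [stimulus_metadata()]), `window`
#'   (a [window_spec()]), `truth` (ground-truth list: `connected`,
#'   `weights`, `q_flags`, `mu`, `kinetics`, per-trial photocurrent
#'   amplitudes `A`, `psc_events`, `psc_taus`), and `config`.
#' @export
simulate_mapping_experiment <- function(n_targets = 100L, connection_prob = 0.1,
                                        photo = photocurrent_population(),
                                        psc = psc_params(),
                                        powers_mW = c(30, 45, 60),
                                        n_reps = 5L, ensemble_size = 1L,
                                        isi_ms = 30, snippet_ms = 45,
                                        context_ms = 5, pulse_ms = 5,
                                        fs = 20000, noise_sd = 5,
                                        seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  connected <- rbinom(n_targets, 1L, connection_prob) == 1L
  weights <- numeric(n_targets)
  weights[connected] <- rgamma(sum(connected), shape = psc$weight_shape,
                               scale = psc$weight_scale)
  traits <- sample_photocurrent_traits(n_targets, photo,
                                       t_on = context_ms,
                                       t_off = context_ms + pulse_ms)
  taus <- cbind(runif(n_targets, psc$tau_rise_range[1], psc$tau_rise_range[2]),
                runif(n_targets, psc$tau_decay_range[1], psc$tau_decay_range[2]))
  locations <- cbind(runif(n_targets, -100, 100), runif(n_targets, -100, 100),
                     runif(n_targets, -50, 50))

  # trial schedule: every (target-or-ensemble, power) x n_reps, shuffled
  if (ensemble_size > 1L) {
    perm <- sample.int(n_targets)
    groups <- split(perm, ceiling(seq_along(perm) / ensemble_size))
  } else {
    groups <- as.list(seq_len(n_targets))
  }
  combos <- expand.grid(g = seq_along(groups), p = seq_along(powers_mW),
                        r = seq_len(n_reps))
  ord <- sample.int(nrow(combos))
  combos <- combos[ord, , drop = FALSE]
  n_trials <- nrow(combos)
  trial_targets <- lapply(combos$g, function(i) as.integer(groups[[i]]))
  trial_powers <- powers_mW[combos$p]
  I_max <- max(powers_mW)

  snip_n <- ms_to_samples(snippet_ms, fs)
  onset_ms <- (seq_len(n_trials) - 1L) * isi_ms + context_ms
  total_ms <- (n_trials - 1L) * isi_ms + snippet_ms
  total_n <- ms_to_samples(total_ms, fs) + 1L
  cont <- numeric(total_n)

  # photocurrent waveform, rendered long enough for the tail to die out
  wf_n <- ms_to_samples(200, fs)
  wf <- photocurrent_waveform(
    opsin_kinetics(O0 = traits$kinetics$O0, O_inf = traits$kinetics$O_inf,
                   tau_o = traits$kinetics$tau_o, R0 = traits$kinetics$R0,
                   R_inf = traits$kinetics$R_inf, tau_r = traits$kinetics$tau_r,
                   t_on = 0, t_off = pulse_ms),
    fs, wf_n, normalize = TRUE)

  add_at <- function(x, start, contrib) {
    idx <- start + seq_along(contrib) - 1L
    keep <- idx <= length(x) & idx >= 1L
    x[idx[keep]] <- x[idx[keep]] + contrib[keep]
    x
  }

  A_trial <- numeric(n_trials)
  ev <- list()
  t_rel_ms <- (seq_len(wf_n) - 1L) / fs * 1000
  for (k in seq_len(n_trials)) {
    on_samp <- ms_to_samples(onset_ms[k], fs) + 1L
    tg <- trial_targets[[k]]
    flagged <- tg[traits$q_flags[tg] == 1L]
    if (length(flagged)) {
      A <- sum(trial_amplitude(traits$mu[flagged], trial_powers[k], I_max,
                               photo$sigma_A))
      if (A > 0) {
        cont <- add_at(cont, on_samp, A * wf)
        A_trial[k] <- A
      }
    }
    for (t_i in tg) {
      if (!connected[t_i]) next
      p_succ <- psc$success_prob_max * trial_powers[k] / I_max
      if (rbinom(1L, 1L, min(p_succ, 1)) == 1L) {
        lat <- .psc_latency(1L, psc, trial_powers[k], I_max)
        ev_start <- on_samp + ms_to_samples(lat, fs)
        kern <- weights[t_i] * psc_kernel(t_rel_ms, taus[t_i, 1], taus[t_i, 2])
        cont <- add_at(cont, ev_start, kern)
        ev[[length(ev) + 1L]] <- data.frame(
          trial = k, target = t_i, time_ms = onset_ms[k] + lat,
          amplitude = weights[t_i], spontaneous = FALSE)
      }
    }
  }
  if (psc$spont_rate_hz > 0) {
    n_spont <- rpois(1L, psc$spont_rate_hz * total_ms / 1000)
    if (n_spont > 0) {
      sp_t <- runif(n_spont, 0, total_ms)
      sp_a <- rgamma(n_spont, shape = psc$weight_shape, scale = psc$weight_scale)
      for (j in seq_len(n_spont)) {
        tr <- runif(1, psc$tau_rise_range[1], psc$tau_rise_range[2])
        td <- runif(1, psc$tau_decay_range[1], psc$tau_decay_range[2])
        kern <- sp_a[j] * psc_kernel(t_rel_ms, tr, td)
        cont <- add_at(cont, ms_to_samples(sp_t[j], fs) + 1L, kern)
        ev[[length(ev) + 1L]] <- data.frame(
          trial = NA_integer_, target = NA_integer_, time_ms = sp_t[j],
          amplitude = sp_a[j], spontaneous = TRUE)
      }
    }
  }
  if (noise_sd > 0) cont <- cont + rnorm(total_n, sd = noise_sd)

  raw <- matrix(0, n_trials, snip_n)
  for (k in seq_len(n_trials)) {
    start <- ms_to_samples(onset_ms[k] - context_ms, fs) + 1L
    raw[k, ] <- cont[start + seq_len(snip_n) - 1L]
  }
  raw <- -raw  # original polarity: inward currents are negative deflections

  # canonical per-target evoked charge (pA*ms): peak weight times the area of
  # the target's unit-peak kernel -- the ground-truth quantity comparable to
  # charge-based weight estimates
  kernel_area <- vapply(seq_len(n_targets), function(i) {
    tt <- seq(0, 200, by = 1000 / fs)              # ms grid
    sum(psc_kernel(tt, taus[i, 1], taus[i, 2])) * (1000 / fs)
  }, numeric(1))
  weights_charge <- weights * kernel_area

  window <- window_spec(t1 = ms_to_samples(context_ms, fs) + 1L,
                        stim_duration_samples = ms_to_samples(pulse_ms, fs),
                        sampling_rate_hz = fs, n_samples = snip_n)
  metadata <- stimulus_metadata(trial_powers, I_max, trial_targets,
                                target_locations_um = locations,
                                trial_times_s = onset_ms / 1000)
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(trial = integer(0), target = integer(0), time_ms = numeric(0),
               amplitude = numeric(0), spontaneous = logical(0))
  list(raw = raw, metadata = metadata, window = window,
       truth = list(connected = connected, weights = weights,
                    weights_charge = weights_charge,
                    q_flags = traits$q_flags, mu = traits$mu,
                    kinetics = traits$kinetics, A = A_trial,
                    psc_events = events, psc_taus = taus,
                    photocurrent_waveform = wf),
       config = list(n_targets = n_targets, connection_prob = connection_prob,
                     powers_mW = powers_mW, n_reps = n_reps,
                     ensemble_size = ensemble_size, isi_ms = isi_ms,
                     snippet_ms = snippet_ms, context_ms = context_ms,
                     pulse_ms = pulse_ms, fs = fs, noise_sd = noise_sd,
                     seed = seed))
}
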