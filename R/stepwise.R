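#' Demixing configuration
#'
#' Tunable parameters of the artifact-removal pipeline. The two knobs that
#' control how aggressive subtraction is are the integration window (longer
#' windows remove more artifact but risk absorbing low-latency PSCs; cap it
#' near 5 ms) and the rank (rank 2 only when artifacts dwarf PSCs).
#'
#' @param rank number of current-trial artifact components (default 1;
#'   values above 2 are allowed but rarely useful).
#' @param gamma per-sample decay factor at the 20 kHz reference rate
#'   (default 0.999); bounds how fast fitted waveforms may decay. Rescaled
#'   automatically at other sampling rates.
#' @param integration_window_ms length of the window after laser onset used
#'   to learn per-trial weights. Default `NULL` = the stimulus duration,
#'   capped at 5 ms.
#' @param t3_offset_ms time after stimulus offset at which the decay
#'   constraint on the current-trial waveform begins (default 10 ms).
#' @param batch_size trials per energy-sorted batch (default 200).
#' @param coord_iters number of coordinate-descent sweeps in step one
#'   (default 10).
#' @param baseline fit the rank-one decaying prior-trial/baseline component
#'   (default TRUE; disabled automatically when there is no pre-stimulus
#'   context).
#' @param noise_margin underapproximation slack in units of the per-sample
#'   noise SD (default 2): the fitted artifact may exceed the recorded trace
#'   by up to `noise_margin * noise_sd` per sample during fitting, so noise
#'   minima do not bias the waveform low (default 3, roughly the expected
#'   minimum of a few hundred Gaussian draws). The assembled artifact is
#'   always clamped below the trace on output.
#' @param stim_floor noise-evidence floor, in noise-SD units (default 3),
#'   applied to two component guards: an artifact component whose peak
#'   reconstruction inside the integration window is below
#'   `stim_floor * noise_sd` is dropped entirely, and a trial's baseline
#'   weight is zeroed unless the trial's own pre-stimulus mean exceeds the
#'   rectified-noise expectation by `stim_floor` standard errors. Both
#'   guards keep the low-rank terms from absorbing weak reliable PSCs in
#'   batches that carry little or no true artifact.
#' @param admm an [admm_settings()].
#' @return object of class `demix_config`.
#' @export
demix_config <- function(rank = 1L, gamma = 0.999, integration_window_ms = NULL,
                         t3_offset_ms = 10, batch_size = 200L,
                         coord_iters = 10L, baseline = TRUE,
                         noise_margin = 3, stim_floor = 3,
                         admm = admm_settings()) {
  if (rank < 1L) pd_stop("rank must be >= 1")
  if (!(gamma > 0 && gamma <= 1)) pd_stop("gamma must lie in (0, 1]")
  structure(list(rank = as.integer(rank), gamma = gamma,
                 integration_window_ms = integration_window_ms,
                 t3_offset_ms = t3_offset_ms, batch_size = as.integer(batch_size),
                 coord_iters = as.integer(coord_iters), baseline = isTRUE(baseline),
                 noise_margin = noise_margin, stim_floor = stim_floor,
                 admm = admm),
            class = "demix_config")
}

#' Windows implied by a configuration
#'
#' Builds the [window_spec()] for a recording from the configuration
#' defaults: integration window = stimulus duration capped at 5 ms unless
#' overridden, decay start 10 ms after stimulus offset.
#'
#' @param Y a [trace_matrix()].
#' @param config a [demix_config()].
#' @return a [window_spec()].
#' @export
default_windows <- function(Y, config = demix_config()) {
  fs <- Y$sampling_rate_hz
  t2 <- if (is.null(config$integration_window_ms)) NULL else
    Y$stim_onset_sample - 1L + ms_to_samples(config$integration_window_ms, fs)
  t3 <- Y$stim_onset_sample + Y$stim_duration_samples +
    ms_to_samples(config$t3_offset_ms, fs)
  window_spec(Y$stim_onset_sample, Y$stim_duration_samples, fs,
              t2 = t2, t3 = min(t3, ncol(Y$values) + 1L),
              n_samples = ncol(Y$values))
}

#' Clipped row-minimum baseline offsets
#'
#' Per-trial constant offsets initialized as the pointwise minimum of the
#' residual over time, clipped at zero. The minimum is the largest constant
#' that still underapproximates the residual row.
#'
#' @param residual N x t2 numeric matrix.
#' @return length-N nonnegative vector.
#' @export
pointwise_min_baseline <- function(residual) {
  residual <- as.matrix(residual)
  pmax(apply(residual, 1L, min), 0)
}

# settings with gamma rescaled to the recording's sampling rate
.gamma_fs <- function(config, fs) gamma_at_rate(config$gamma, fs)

#' Step one: windowed fit of weights, baselines and offsets
#'
#' Fits the stepwise model on the integration window `[1, t2]` only:
#' a rank-one exponentially decaying baseline term (prior-trial leftovers),
#' `rank` current-trial artifact components learned on the laser-on samples,
#' and per-trial constant offsets, all tied together by the elementwise
#' underapproximation constraint. Weights learned here are frozen in step
#' two. Coordinate descent sweeps update each term against the residual of
#' the others; a sweep that fails to decrease the residual norm is rolled
#' back, so the objective is non-increasing across sweeps.
#'
#' @param Y_window rectified N x t2 matrix (the snippet up to the end of the
#'   integration window).
#' @param window a [window_spec()].
#' @param config a [demix_config()].
#' @param noise_sd per-sample noise SD (pA) used for the noise-margin slack
#'   on the underapproximation constraint; 0 disables the slack.
#' @return object of class `step_one_estimate` with fields `U_base`,
#'   `V_base`, `U_stim` (N x rank), `V_stim` (rank x t2), `beta`, and
#'   `diagnostics`.
#' @export
fit_step_one <- function(Y_window, window, config = demix_config(),
                         noise_sd = 0) {
  Yw <- as.matrix(Y_window)
  n <- nrow(Yw)
  t1 <- window$t1
  t2 <- ncol(Yw)
  if (window$t2 != t2)
    pd_stop("Y_window has %d columns but window$t2 = %d", t2, window$t2)
  fs <- window$sampling_rate_hz
  g <- .gamma_fs(config, fs)
  R <- config$rank
  settings <- config$admm
  slack <- config$noise_margin * noise_sd

  use_base <- config$baseline && t1 >= 2L
  if (config$baseline && t1 < 2L)
    warning("no pre-stimulus context (t1 = 1): baseline component disabled")

  U_base <- matrix(0, n, 1L)
  V_base <- numeric(t2)
  if (use_base) {
    pre <- Yw[, seq_len(t1 - 1L), drop = FALSE]
    fb <- nmu_decreasing(pre, constraint = decay_constraint(g, 1L),
                         slack = slack, settings = settings)
    if (sum(fb$v) > 0) {
      tail_len <- t2 - (t1 - 1L)
      v_ext <- c(fb$v, fb$v[t1 - 1L] * g^seq_len(tail_len))
      fb2 <- nmu_decreasing(Yw, u_init = fb$u, v_init = v_ext,
                            constraint = decay_constraint(g, 1L),
                            update_u = FALSE, slack = slack,
                            settings = settings)
      U_base[, 1L] <- fb$u
      V_base <- fb2$v
    } else {
      use_base <- FALSE
    }
  }
  base_mat <- tcrossprod(U_base[, 1L], V_base)

  # current-trial components, learned on the laser-on part of the window
  stim_cols <- t1:t2
  cons_stim <- if (window$t3 <= t2)
    decay_constraint(g, window$t3 - t1 + 1L) else NULL
  # offsets first: with no stimulus components yet, the pointwise-min
  # residual is exactly the constant-offset content (components are zero
  # before laser onset, and rectified recordings have near-zero row minima,
  # so this is a no-op on real data but stops the rank-one term from
  # swallowing clean pedestals)
  beta <- pointwise_min_baseline(Yw - base_mat)
  U_stim <- matrix(0, n, R)
  V_stim <- matrix(0, R, t2)
  resid <- pmax(Yw[, stim_cols, drop = FALSE] -
                  base_mat[, stim_cols, drop = FALSE] - beta, 0)
  for (r in seq_len(R)) {
    fr <- nmu_decreasing(resid, constraint = cons_stim, slack = slack,
                         settings = settings)
    U_stim[, r] <- fr$u
    V_stim[r, stim_cols] <- fr$v
    resid <- pmax(resid - tcrossprod(fr$u, fr$v), 0)
  }
  stim_mat <- U_stim %*% V_stim
  beta <- pointwise_min_baseline(Yw - base_mat - stim_mat)

  resid_norm <- function() {
    sqrt(sum((Yw - tcrossprod(U_base[, 1L], V_base) - U_stim %*% V_stim - beta)^2))
  }
  norms <- resid_norm()
  for (k in seq_len(config$coord_iters)) {
    snap <- list(U_base = U_base, V_base = V_base, U_stim = U_stim,
                 V_stim = V_stim, beta = beta)
    if (use_base) {
      Yt <- pmax(Yw - U_stim %*% V_stim - beta, 0)
      fb <- nmu_decreasing(Yt, u_init = U_base[, 1L], v_init = V_base,
                           constraint = decay_constraint(g, 1L),
                           slack = slack, settings = settings)
      U_base[, 1L] <- fb$u
      V_base <- fb$v
    }
    base_mat <- tcrossprod(U_base[, 1L], V_base)
    beta <- pointwise_min_baseline(Yw - base_mat - U_stim %*% V_stim)
    for (r in seq_len(R)) {
      others <- U_stim[, -r, drop = FALSE] %*% V_stim[-r, , drop = FALSE]
      Yt <- pmax(Yw[, stim_cols, drop = FALSE] -
                   base_mat[, stim_cols, drop = FALSE] -
                   others[, stim_cols, drop = FALSE] - beta, 0)
      fr <- nmu_decreasing(Yt, u_init = U_stim[, r],
                           v_init = V_stim[r, stim_cols],
                           constraint = cons_stim, slack = slack,
                           settings = settings)
      U_stim[, r] <- fr$u
      V_stim[r, ] <- 0
      V_stim[r, stim_cols] <- fr$v
    }
    new_norm <- resid_norm()
    if (new_norm > norms[length(norms)] * (1 + 1e-12)) {
      # sweep made things worse (ADMM subproblems are inexact): roll back
      U_base <- snap$U_base; V_base <- snap$V_base
      U_stim <- snap$U_stim; V_stim <- snap$V_stim; beta <- snap$beta
      pd_log(2L, "step one: sweep %d rolled back", k)
      break
    }
    norms <- c(norms, new_norm)
    pd_log(2L, "step one: sweep %d residual %.4g", k, new_norm)
  }
  # component guards: refuse to subtract what cannot be distinguished from
  # noise (see demix_config). (1) a whole artifact component whose peak
  # reconstruction inside the integration window is below the floor;
  # (2) per-trial baseline weights whose modeled prior-trial tail at snippet
  # start is below the floor -- a genuine leftover tail is large there, and
  # a sub-noise baseline envelope happily absorbs weak PSCs instead.
  dropped <- logical(R)
  if (noise_sd > 0) {
    floor_pa <- config$stim_floor * noise_sd
    for (r in seq_len(R)) {
      peak_r <- max(U_stim[, r]) * max(V_stim[r, ])
      if (peak_r < floor_pa) {
        U_stim[, r] <- 0
        V_stim[r, ] <- 0
        dropped[r] <- TRUE
        pd_log(2L, "step one: component %d dropped (window peak %.2f pA < %g sigma)",
               r, peak_r, config$stim_floor)
      }
    }
    if (use_base && t1 >= 2L) {
      # keep a trial's baseline weight only when its own pre-stimulus data
      # show more signal than rectified noise: mean of rectified N(0, sd)
      # is sd/sqrt(2*pi) with per-sample SD ~0.583*sd. Without evidence in
      # the context window the "tail" is an absorber of mid-trial structure
      # (weak PSCs), not a leftover photocurrent.
      m <- t1 - 1L
      floor_pre <- noise_sd / sqrt(2 * pi) +
        config$stim_floor * 0.583 * noise_sd / sqrt(m)
      weak <- rowMeans(Yw[, seq_len(m), drop = FALSE]) < floor_pre
      U_base[weak, 1L] <- 0
    }
    beta <- pointwise_min_baseline(
      Yw - tcrossprod(U_base[, 1L], V_base) - U_stim %*% V_stim)
  }
  structure(list(U_base = U_base, V_base = V_base,
                 U_stim = U_stim, V_stim = V_stim, beta = beta,
                 use_base = use_base, window = window,
                 diagnostics = list(sweep_residuals = norms,
                                    dropped_components = dropped)),
            class = "step_one_estimate")
}

#' Step two: full-trace waveform extension and artifact assembly
#'
#' With all per-trial weights and offsets frozen from step one, re-fits the
#' temporal waveforms over the whole snippet: the baseline waveform under
#' the decay constraint everywhere, then each artifact component with decay
#' enforced from `t3` on (so the tail cannot absorb the following trial),
#' deflating components in order of decreasing energy. Assembles the
#' artifact reconstruction and the demixed (artifact-subtracted) traces.
#'
#' @param Y a [trace_matrix()] or rectified N x T matrix.
#' @param step1 a `step_one_estimate` fitted on the same trials.
#' @param window a [window_spec()].
#' @param config a [demix_config()].
#' @param noise_sd per-sample noise SD (pA) for the noise-margin slack.
#' @return object of class `photocurrent_estimate`: full-length `V_base`,
#'   `V_stim`, the frozen `U_base`, `U_stim`, `beta`, plus `artifact`
#'   (N x T), `demixed` (N x T, rectified domain) and `diagnostics`.
#' @export
fit_step_two <- function(Y, step1, window, config = demix_config(),
                         noise_sd = 0) {
  vals <- if (inherits(Y, "trace_matrix")) Y$values else as.matrix(Y)
  n <- nrow(vals)
  T_ <- ncol(vals)
  if (n != nrow(step1$U_stim))
    pd_stop("trial count mismatch: Y has %d rows, step one was fit on %d",
            n, nrow(step1$U_stim))
  fs <- window$sampling_rate_hz
  g <- .gamma_fs(config, fs)
  settings <- config$admm
  slack <- config$noise_margin * noise_sd
  t2 <- length(step1$V_base)
  R <- ncol(step1$U_stim)

  extend_decay <- function(v, len) {
    if (length(v) >= len) return(v[seq_len(len)])
    c(v, v[length(v)] * g^seq_len(len - length(v)))
  }

  V_base_full <- numeric(T_)
  if (step1$use_base && sum(step1$V_base) > 0) {
    fb <- nmu_decreasing(vals, u_init = step1$U_base[, 1L],
                         v_init = extend_decay(step1$V_base, T_),
                         constraint = decay_constraint(g, 1L),
                         update_u = FALSE, slack = slack,
                         settings = settings)
    V_base_full <- fb$v
  }
  base_mat <- tcrossprod(step1$U_base[, 1L], V_base_full)
  X <- pmax(vals - base_mat - step1$beta, 0)

  cons_stim <- if (window$t3 <= T_) decay_constraint(g, window$t3) else NULL
  V_stim_full <- matrix(0, R, T_)
  ord <- order(rowSums(step1$V_stim^2), decreasing = TRUE)
  for (r in ord) {
    u_r <- step1$U_stim[, r]
    if (sum(u_r) == 0 || sum(step1$V_stim[r, ]) == 0) next
    fr <- nmu_decreasing(X, u_init = u_r,
                         v_init = extend_decay(step1$V_stim[r, ], T_),
                         constraint = cons_stim, update_u = FALSE,
                         slack = slack, settings = settings)
    V_stim_full[r, ] <- fr$v
    X <- pmax(X - tcrossprod(u_r, fr$v), 0)
  }
  artifact <- base_mat + step1$U_stim %*% V_stim_full + step1$beta
  raw_resid <- vals - artifact
  demixed <- pmax(raw_resid, 0)
  max_overshoot <- max(artifact - vals)
  # the solver satisfies the underapproximation to ADMM tolerance; clamp the
  # assembled reconstruction so the contract holds exactly (pre-clamp
  # violation is kept in the diagnostics)
  artifact <- pmin(artifact, vals)
  structure(list(U_base = step1$U_base, V_base = V_base_full,
                 U_stim = step1$U_stim, V_stim = V_stim_full,
                 beta = step1$beta, artifact = artifact, demixed = demixed,
                 window = window,
                 diagnostics = list(
                   clipped_negative_mass = -sum(pmin(raw_resid, 0)),
                   max_overshoot = max_overshoot)),
            class = "photocurrent_estimate")
}

#' Subtract the estimated artifact in the caller's polarity
#'
#' Returns demixed traces in the original sign convention and without the
#' rectification clip: samples that were clipped when building the
#' rectified matrix are restored from the raw input minus the artifact, so
#' sub-baseline noise survives subtraction.
#'
#' @param Y_raw N x T signed traces as originally recorded.
#' @param estimate a `photocurrent_estimate` (or any object with an
#'   `artifact` matrix in the rectified, inward-positive domain).
#' @param polarity sign convention of `Y_raw`.
#' @return N x T matrix of demixed traces in the original polarity.
#' @export
subtract_photocurrent <- function(Y_raw, estimate,
                                  polarity = c("inward_negative", "inward_positive")) {
  polarity <- match.arg(polarity)
  Y_raw <- as.matrix(Y_raw)
  artifact <- estimate$artifact
  if (!all(dim(Y_raw) == dim(artifact)))
    pd_stop("shape mismatch: raw %dx%d vs artifact %dx%d",
            nrow(Y_raw), ncol(Y_raw), nrow(artifact), ncol(artifact))
  if (polarity == "inward_negative") Y_raw + artifact else Y_raw - artifact
}

#' Remove photocurrent artifacts from a mapping experiment
#'
#' End-to-end driver: rectifies the raw traces, orders trials by
#' stimulus-window energy, partitions them into batches, runs the two-step
#' constrained fit per batch, and stitches per-trial artifact and demixed
#' traces back into the original trial order. Batching by energy groups
#' trials with similar artifact size and kinetics, which the rank-one model
#' captures better than the whole heterogeneous experiment at once.
#'
#' @param raw N x T signed traces (original polarity), or a
#'   [trace_matrix()] that is already rectified.
#' @param polarity sign convention of `raw` (ignored for a
#'   [trace_matrix()] input).
#' @param sampling_rate_hz,stim_onset_sample,stim_duration_samples snippet
#'   geometry (ignored for a [trace_matrix()] input).
#' @param config a [demix_config()].
#' @param window optional [window_spec()]; default derived from the
#'   configuration.
#' @return object of class `demix_fit` with fields `Y` (the rectified
#'   [trace_matrix()]), `partition`, `batches` (list of per-batch
#'   `photocurrent_estimate`s), `artifact` and `demixed_rectified`
#'   (N x T, rectified domain, original trial order), `demixed` (original
#'   polarity) and a per-batch `diagnostics` data frame.
#' @export
remove_photocurrents <- function(raw,
                                 polarity = c("inward_negative", "inward_positive"),
                                 sampling_rate_hz = 20000,
                                 stim_onset_sample = 1L,
                                 stim_duration_samples = 1L,
                                 config = demix_config(),
                                 window = NULL) {
  if (inherits(raw, "trace_matrix")) {
    Y <- raw
    raw_vals <- if (Y$input_polarity == "inward_negative") -Y$values else Y$values
  } else {
    polarity <- match.arg(polarity)
    raw_vals <- as.matrix(raw)
    Y <- rectify_traces(raw_vals, polarity, sampling_rate_hz,
                        stim_onset_sample, stim_duration_samples)
  }
  if (is.null(window)) window <- default_windows(Y, config)
  n <- nrow(Y$values)
  T_ <- ncol(Y$values)
  energies <- stim_energy(Y, window)
  part <- make_batches(energies, config$batch_size)
  # robust per-sample noise SD from the signed pre-stimulus context
  # (negative half only, so artifact tails cannot inflate it)
  noise_sd <- 0
  if (window$t1 >= 2L) {
    signed <- if (Y$input_polarity == "inward_negative") -raw_vals else raw_vals
    pre <- signed[, seq_len(window$t1 - 1L)]
    neg <- pre[pre < 0]
    if (length(neg) > 20L) noise_sd <- stats::median(abs(neg)) / 0.6745
  }

  artifact <- matrix(0, n, T_)
  batches <- vector("list", length(part$sizes))
  diags <- vector("list", length(part$sizes))
  offset <- 0L
  for (b in seq_along(part$sizes)) {
    idx <- part$order[offset + seq_len(part$sizes[b])]
    offset <- offset + part$sizes[b]
    Yb <- Y$values[idx, , drop = FALSE]
    est <- tryCatch({
      s1 <- fit_step_one(Yb[, seq_len(window$t2), drop = FALSE], window,
                         config, noise_sd = noise_sd)
      fit_step_two(Yb, s1, window, config, noise_sd = noise_sd)
    }, error = function(e) {
      pd_stop("batch %d (%d trials): %s", b, length(idx), conditionMessage(e))
    })
    artifact[idx, ] <- est$artifact
    batches[[b]] <- est
    pre <- sum(Yb[, window$t1:(window$t1 + window$stim_duration_samples - 1L)])
    post <- sum(est$demixed[, window$t1:(window$t1 + window$stim_duration_samples - 1L)])
    diags[[b]] <- data.frame(
      batch = b, n_trials = length(idx),
      max_overshoot = est$diagnostics$max_overshoot,
      clipped_negative_mass = est$diagnostics$clipped_negative_mass,
      subtracted_fraction = if (pre > 0) 1 - post / pre else 0)
    pd_log(1L, "batch %d/%d: %d trials, subtracted fraction %.3f",
           b, length(part$sizes), length(idx), diags[[b]]$subtracted_fraction)
  }
  demixed_rect <- pmax(Y$values - artifact, 0)
  demixed <- subtract_photocurrent(raw_vals, list(artifact = artifact),
                                   Y$input_polarity)
  structure(list(Y = Y, window = window, config = config, partition = part,
                 batches = batches, artifact = artifact,
                 demixed_rectified = demixed_rect, demixed = demixed,
                 diagnostics = do.call(rbind, diags)),
            class = "demix_fit")
}

#' @export
print.demix_fit <- function(x, ...) {
  cat(sprintf("<demix_fit> %d trials x %d samples, %d batches\n",
              nrow(x$artifact), ncol(x$artifact), length(x$batches)))
  print(x$diagnostics, row.names = FALSE)
  invisible(x)
}
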