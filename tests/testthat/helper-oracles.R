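# Independent brute-force oracles used to validate the optimization kernels.
# These deliberately share no code with the package implementations.

# Euclidean projection onto { q : q[i] <= gamma * q[i-1], i > s } by
# enumerating KKT active sets of the quadratic program (exact for the
# strictly convex objective). Only viable for small n.
oracle_project_decay <- function(x, gamma, s = 1L) {
  n <- length(x)
  rows <- (s + 1L):n
  if (s >= n) return(x)
  m <- length(rows)
  A <- matrix(0, m, n)
  for (j in seq_len(m)) {
    A[j, rows[j] - 1L] <- -gamma
    A[j, rows[j]] <- 1
  }
  best <- NULL
  best_obj <- Inf
  for (mask in 0:(2^m - 1)) {
    act <- which(bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0)
    if (length(act) == 0) {
      q <- x
      mu_ok <- TRUE
    } else {
      As <- A[act, , drop = FALSE]
      K <- rbind(cbind(diag(n), t(As)),
                 cbind(As, matrix(0, length(act), length(act))))
      rhs <- c(x, numeric(length(act)))
      sol <- tryCatch(solve(K, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      q <- sol[seq_len(n)]
      mu <- sol[-seq_len(n)]
      mu_ok <- all(mu >= -1e-8)
    }
    feas <- all(A %*% q <= 1e-8)
    if (feas && mu_ok) {
      obj <- sum((q - x)^2)
      if (obj < best_obj) {
        best_obj <- obj
        best <- q
      }
    }
  }
  best
}

# Nonnegative (ridge) least squares min ||A x - b||^2 + lambda ||x||^2 by
# enumerating which variables are clamped at zero; KKT-checked.
oracle_nnls_ridge <- function(A, b, lambda = 0) {
  n <- ncol(A)
  G <- crossprod(A) + lambda * diag(n)
  h <- drop(crossprod(A, b))
  best <- NULL
  best_obj <- Inf
  for (mask in 0:(2^n - 1)) {
    free <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    x <- numeric(n)
    if (length(free)) {
      sol <- tryCatch(solve(G[free, free, drop = FALSE], h[free]),
                      error = function(e) NULL)
      if (is.null(sol)) next
      x[free] <- sol
    }
    if (any(x < -1e-9)) next
    grad <- G %*% x - h
    if (any(grad[setdiff(seq_len(n), free)] < -1e-8)) next
    obj <- sum((A %*% x - b)^2) + lambda * sum(x^2)
    if (obj < best_obj) {
      best_obj <- obj
      best <- pmax(x, 0)
    }
  }
  best
}

# Small synthetic batch: scaled copies of a decaying waveform plus optional
# constant offsets, PSCs and noise. Returns the batch and its ground truth.
make_waveform_batch <- function(n_trials = 50, t2 = 200, t1 = 101,
                                amplitudes = NULL, offsets = NULL,
                                noise_sd = 0, fs = 20000, seed = 1) {
  set.seed(seed)
  if (is.null(amplitudes)) amplitudes <- rgamma(n_trials, 2, scale = 250)
  if (is.null(offsets)) offsets <- numeric(n_trials)
  kin <- opsin_kinetics(O0 = 0, O_inf = 0.9, tau_o = 2, R0 = 1, R_inf = 0.6,
                        tau_r = 12, t_on = (t1 - 1) / fs * 1000,
                        t_off = (t1 - 1) / fs * 1000 + 5)
  wf <- photocurrent_waveform(kin, fs, t2, normalize = TRUE)
  Y <- outer(amplitudes, wf) + offsets
  if (noise_sd > 0) Y <- Y + matrix(rnorm(n_trials * t2, sd = noise_sd),
                                    n_trials, t2)
  list(Y = pmax(Y, 0), amplitudes = amplitudes, offsets = offsets,
       waveform = wf, window = window_spec(t1, ms_to_samples(5, fs), fs,
                                           t2 = t2, n_samples = t2))
}

# Compact simulated experiment for unit tests (seconds, not minutes).
small_experiment <- function(seed = 1, n_targets = 30L, p = 0.1, ...) {
  simulate_mapping_experiment(n_targets = n_targets, n_reps = 3L,
                              photo = photocurrent_population(p = p),
                              seed = seed, ...)
}

fit_of <- function(sim, config = demix_config()) {
  remove_photocurrents(sim$raw, "inward_negative",
                       stim_onset_sample = sim$window$t1,
                       stim_duration_samples = sim$window$stim_duration_samples,
                       config = config)
}
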