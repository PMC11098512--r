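test_that("pointwise_min_baseline takes clipped row minima", {
  expect_equal(pointwise_min_baseline(rbind(c(2, 3), c(1, 4))), c(2, 1))
  expect_equal(pointwise_min_baseline(rbind(c(-1, 5))), 0)
  expect_equal(pointwise_min_baseline(matrix(0, 3, 4)), rep(0, 3))
})

test_that("step one recovers amplitudes and constant offsets", {
  set.seed(21)
  b <- runif(50, 5, 40)
  batch <- make_waveform_batch(n_trials = 50, offsets = b, seed = 21)
  cfg <- demix_config(baseline = FALSE)
  s1 <- fit_step_one(batch$Y, batch$window, cfg)
  est_A <- s1$U_stim[, 1] * max(s1$V_stim[1, ])
  expect_gt(cor(est_A, batch$amplitudes), 0.99)
  expect_lt(mean(abs(s1$beta - b)), 0.05 * mean(b))
})

test_that("all-zero window yields all-zero factors", {
  w <- window_spec(t1 = 101, stim_duration_samples = 100, t2 = 200,
                   n_samples = 200)
  s1 <- fit_step_one(matrix(0, 10, 200), w)
  expect_equal(s1$U_stim, matrix(0, 10, 1))
  expect_equal(s1$beta, rep(0, 10))
  expect_equal(sum(s1$V_base), 0)
})

test_that("integration window separates photocurrents from delayed PSCs", {
  set.seed(22)
  fs <- 20000
  t1 <- 101
  t2 <- 200
  kin <- opsin_kinetics(t_on = 5, t_off = 10)
  wf <- photocurrent_waveform(kin, fs, t2, normalize = TRUE)
  n_photo <- 30
  n_psc <- 20
  A <- rgamma(n_photo, 2, scale = 250)
  Y <- rbind(outer(A, wf),
             t(vapply(seq_len(n_psc), function(i) {
               60 * psc_kernel(((seq_len(t2) - t1) / fs * 1000) - 3.5,
                               tau_rise = 1, tau_decay = 10)
             }, numeric(t2))))
  w <- window_spec(t1, 100, fs, t2 = t2, n_samples = t2)
  s1 <- fit_step_one(pmax(Y, 0), w, demix_config(baseline = FALSE))
  u_photo <- mean(s1$U_stim[seq_len(n_photo), 1])
  u_psc <- s1$U_stim[n_photo + seq_len(n_psc), 1]
  expect_true(all(u_psc < 0.05 * u_photo))
})

test_that("step two removes nearly all energy of pure noisy photocurrents", {
  set.seed(23)
  fs <- 20000
  T_ <- 900
  t1 <- 101
  kin <- opsin_kinetics(t_on = 5, t_off = 10)
  wf <- photocurrent_waveform(kin, fs, T_, normalize = TRUE)
  A <- runif(60, 300, 800)    # typical direct-excitation range, 0.3-0.8 nA
  sd_noise <- 0.01 * max(outer(A, wf))
  Y <- pmax(outer(A, wf) + matrix(rnorm(60 * T_, sd = sd_noise), 60, T_), 0)
  w <- window_spec(t1, 100, fs, n_samples = T_)
  cfg <- demix_config()
  s1 <- fit_step_one(Y[, 1:w$t2], w, cfg, noise_sd = sd_noise)
  s2 <- fit_step_two(Y, s1, w, cfg, noise_sd = sd_noise)
  stim <- t1:(t1 + 99)
  frac_removed <- 1 - rowSums(s2$demixed[, stim]) / rowSums(Y[, stim])
  expect_true(all(frac_removed >= 0.95))
})

test_that("step two leaves photocurrent-free traces essentially untouched", {
  set.seed(24)
  fs <- 20000
  T_ <- 900
  t1 <- 101
  kin <- opsin_kinetics(t_on = 5, t_off = 10)
  wf <- photocurrent_waveform(kin, fs, T_, normalize = TRUE)
  t_ms <- (seq_len(T_) - t1) / fs * 1000
  psc <- 80 * psc_kernel(t_ms - 4, tau_rise = 1, tau_decay = 10)
  A <- c(rgamma(40, 2, scale = 300), rep(0, 20))
  Y <- outer(A, wf)
  Y[41:60, ] <- Y[41:60, ] + matrix(psc, 20, T_, byrow = TRUE)
  Y <- pmax(Y + matrix(rnorm(60 * T_, sd = 2), 60, T_), 0)
  w <- window_spec(t1, 100, fs, n_samples = T_)
  cfg <- demix_config()
  s1 <- fit_step_one(Y[, 1:w$t2], w, cfg, noise_sd = 2)
  s2 <- fit_step_two(Y, s1, w, cfg, noise_sd = 2)
  ch_pre <- charge_transfer(Y[41:60, ], w)
  ch_post <- charge_transfer(s2$demixed[41:60, ], w)
  expect_true(all(abs(ch_post - ch_pre) / ch_pre < 0.10))
})

test_that("step one sweeps never increase the residual", {
  set.seed(25)
  batch <- make_waveform_batch(n_trials = 40, noise_sd = 5, seed = 25)
  s1 <- fit_step_one(batch$Y, batch$window, demix_config(), noise_sd = 5)
  res <- s1$diagnostics$sweep_residuals
  expect_true(all(diff(res) <= 1e-8 * res[1]))
})

test_that("subtract_photocurrent restores the caller's polarity", {
  est0 <- list(artifact = matrix(0, 2, 3))
  raw <- rbind(c(-1, 2, -3), c(0.5, -0.5, 1))
  expect_equal(subtract_photocurrent(raw, est0, "inward_negative"), raw)
  # inward_negative raw -y with artifact a -> -(y - a)
  est <- list(artifact = rbind(c(2, 0, 1), c(0, 0, 0)))
  out <- subtract_photocurrent(rbind(c(-5, -1, -2), c(-1, -1, -1)), est,
                               "inward_negative")
  expect_equal(out[1, ], c(-(5 - 2), -1, -(2 - 1)))
  expect_error(subtract_photocurrent(matrix(0, 3, 3), est), "mismatch")
})

test_that("remove_photocurrents is the identity on zero traces", {
  fit <- remove_photocurrents(matrix(0, 20, 300), "inward_negative",
                              stim_onset_sample = 101,
                              stim_duration_samples = 100)
  expect_equal(fit$demixed, matrix(0, 20, 300))
  expect_equal(fit$artifact, matrix(0, 20, 300))
})

test_that("demixing is invariant to trial order", {
  sim <- small_experiment(seed = 26)
  fit1 <- fit_of(sim)
  set.seed(99)
  perm <- sample.int(nrow(sim$raw))
  fit2 <- remove_photocurrents(sim$raw[perm, ], "inward_negative",
                               stim_onset_sample = sim$window$t1,
                               stim_duration_samples = sim$window$stim_duration_samples)
  back <- fit2$demixed[order(perm), ]
  expect_lt(max(abs(back - fit1$demixed)), 1e-6)
})

test_that("fitted batches satisfy the model constraints", {
  sim <- small_experiment(seed = 27)
  cfg <- demix_config()
  fit <- fit_of(sim, cfg)
  g <- gamma_at_rate(cfg$gamma, sim$window$sampling_rate_hz)
  w <- fit$window
  for (est in fit$batches) {
    expect_true(all(est$U_stim >= 0))
    expect_true(all(est$V_stim >= -1e-12))
    expect_true(all(est$beta >= 0))
    # decay constraints hold exactly
    vb <- est$V_base
    if (sum(vb) > 0)
      expect_true(all(vb[-1] <= g * vb[-length(vb)] + 1e-9))
    for (r in seq_len(nrow(est$V_stim))) {
      vs <- est$V_stim[r, ]
      if (w$t3 < length(vs) && sum(vs) > 0) {
        suf <- vs[w$t3:length(vs)]
        expect_true(all(suf[-1] <= g * suf[-length(suf)] + 1e-9))
      }
    }
  }
  # global conservation: rectified data = artifact + rectified demixed
  expect_lt(max(abs(fit$Y$values - fit$artifact - fit$demixed_rectified)), 1e-9)
  expect_true(all(fit$artifact <= fit$Y$values + 1e-12))
})

test_that("baseline component is disabled without pre-stimulus context", {
  Y <- pmax(matrix(rnorm(200, 5), 10, 20), 0)
  w <- window_spec(t1 = 1, stim_duration_samples = 20, t2 = 20, t3 = 21,
                   n_samples = 20)
  expect_warning(s1 <- fit_step_one(Y, w, demix_config()), "baseline")
  expect_false(s1$use_base)
})
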