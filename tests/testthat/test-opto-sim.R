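test_that("photocurrent waveform follows the gating model closed forms", {
  fs <- 20000
  kin <- opsin_kinetics(O0 = 0.2, O_inf = 1, tau_o = 2, R0 = 1, R_inf = 0.5,
                       tau_r = 10, t_on = 0, t_off = 5)
  w <- photocurrent_waveform(kin, fs, 400)
  # closed-form at t = 2 ms during the pulse
  expect_equal(w[2 * 20 + 1], (1 - 0.8 * exp(-1)) * (0.5 + 0.5 * exp(-0.2)),
               tolerance = 1e-12)
  # zero before onset; at exactly t_on the gate is open (theta(0) = 1) but
  # starts from O0 = 0, so the current rises from zero on the next sample
  kin2 <- opsin_kinetics(t_on = 5, t_off = 10)
  w2 <- photocurrent_waveform(kin2, fs, 400)
  expect_true(all(w2[1:(5 * 20)] == 0))
  expect_equal(w2[5 * 20 + 1], 0)
  expect_gt(w2[5 * 20 + 2], 0)
  # with O0 > 0, theta(0) = 1 gives a nonzero value at t_on itself
  kin3 <- opsin_kinetics(O0 = 0.3, t_on = 5, t_off = 10)
  expect_gt(photocurrent_waveform(kin3, fs, 400)[5 * 20 + 1], 0)
})

test_that("waveform is continuous at pulse offset and nonnegative", {
  set.seed(31)
  fs <- 20000
  for (i in 1:10) {
    k <- opsin_kinetics(O0 = runif(1, 0, 0.3), O_inf = runif(1, 0.5, 1),
                        tau_o = runif(1, 1, 5), R0 = 1,
                        R_inf = runif(1, 0.3, 1), tau_r = runif(1, 5, 40),
                        t_on = 1, t_off = 3)
    w <- photocurrent_waveform(k, fs, 200)
    # off-branch value at exactly t_off equals the on-branch limit
    on_limit <- (k$O_inf - (k$O_inf - k$O0) * exp(-(k$t_off - k$t_on) / k$tau_o)) *
      (k$R_inf - (k$R_inf - k$R0) * exp(-(k$t_off - k$t_on) / k$tau_r))
    i_off <- k$t_off / 1000 * fs + 1
    expect_lt(abs(w[i_off] - on_limit), 1e-9)
    expect_true(all(w >= 0))
  }
})

test_that("long-pulse limit approaches O_inf * R_inf", {
  kin <- opsin_kinetics(O0 = 0, O_inf = 0.8, tau_o = 2, R0 = 1, R_inf = 0.4,
                        tau_r = 10, t_on = 0, t_off = 500)
  w <- photocurrent_waveform(kin, 20000, 400 * 20)
  expect_equal(w[length(w)], 0.8 * 0.4, tolerance = 1e-3)
})

test_that("population traits follow the stated distributions", {
  set.seed(32)
  z <- sample_photocurrent_traits(100, photocurrent_population(p = 0))
  expect_true(all(z$q_flags == 0) && all(z$mu == 0))

  n <- 1e4
  z1 <- sample_photocurrent_traits(n, photocurrent_population(p = 1,
                                                              k_photo = 2,
                                                              theta_photo = 250))
  se <- sqrt(2 * 250^2 / n)  # SD of gamma(2, 250) mean
  expect_lt(abs(mean(z1$mu) - 500), 3 * se)

  z2 <- sample_photocurrent_traits(n, photocurrent_population(p = 0.1))
  expect_lt(abs(mean(z2$q_flags) - 0.1), 3 * sqrt(0.1 * 0.9 / n))
})

test_that("trial amplitudes scale with power and clip at zero", {
  expect_equal(trial_amplitude(500, 60, 60, sigma_A = 0), 500)
  expect_equal(trial_amplitude(500, 0, 60, sigma_A = 0), 0)
  expect_error(trial_amplitude(500, 0, 0), "I_max")
  set.seed(33)
  n <- 1e4
  a <- trial_amplitude(rep(500, n), 30, 60, sigma_A = 25)
  expect_lt(abs(mean(a) - 250), 3 * 25 / sqrt(n))
  expect_true(all(a >= 0))
})

test_that("psc kernel peaks at the closed-form time", {
  t_star <- 1 * 10 / (10 - 1) * log(10)   # tau_rise 1, tau_decay 10
  expect_equal(t_star, 2.558, tolerance = 1e-3)
  tt <- seq(0, 20, by = 1e-4)
  k <- psc_kernel(tt, 1, 10)
  expect_equal(tt[which.max(k)], t_star, tolerance = 1e-3)
  expect_equal(max(k), 1)                 # unit peak
  expect_true(all(psc_kernel(seq(-5, -0.1, by = 0.1), 1, 10) == 0))
})

test_that("psc trains honor connectivity, success and latency rules", {
  set.seed(34)
  # unconnected, no spontaneous -> exactly zero
  z <- simulate_psc_train(connected = c(FALSE, FALSE), weights = c(0, 0),
                          powers = rep(60, 6), targets = rep(1:2, 3),
                          psc = psc_params(spont_rate_hz = 0),
                          n_samples = 900)
  expect_equal(z$traces, matrix(0, 6, 900))
  expect_equal(nrow(z$events), 0L)
  # degenerate latency: success prob 1, zero jitter -> onset exactly at
  # t_on + 3 ms
  z2 <- simulate_psc_train(connected = TRUE, weights = 50,
                           powers = rep(60, 5), targets = rep(1L, 5),
                           psc = psc_params(latency_jitter_ms = 1e-12,
                                            success_prob_max = 1,
                                            spont_rate_hz = 0),
                           n_samples = 900, t_on_ms = 5)
  expect_equal(nrow(z2$events), 5L)
  expect_true(all(abs(z2$events$time_ms - 8) < 1e-6))
})

test_that("simulated experiments have the documented geometry", {
  sim <- simulate_mapping_experiment(n_targets = 10, n_reps = 2, seed = 35)
  expect_equal(ncol(sim$raw), 900L)        # 45 ms at 20 kHz
  expect_equal(nrow(sim$raw), 10 * 3 * 2)  # targets x powers x reps
  expect_equal(sim$window$t1, 101L)
  # all sources off -> silence
  sim0 <- simulate_mapping_experiment(n_targets = 5, n_reps = 2,
                                      connection_prob = 0,
                                      photo = photocurrent_population(p = 0),
                                      psc = psc_params(spont_rate_hz = 0),
                                      noise_sd = 0, seed = 36)
  expect_equal(sim0$raw, matrix(0, 30, 900))
})

test_that("simulation is exactly reproducible from its seed", {
  a <- simulate_mapping_experiment(n_targets = 8, n_reps = 2, seed = 37)
  b <- simulate_mapping_experiment(n_targets = 8, n_reps = 2, seed = 37)
  expect_identical(a$raw, b$raw)
  expect_identical(a$truth$A, b$truth$A)
  c_ <- simulate_mapping_experiment(n_targets = 8, n_reps = 2, seed = 38)
  expect_false(identical(a$raw, c_$raw))
})

test_that("short ISIs leave prior-trial tails in the next snippet", {
  # every target evokes photocurrent with slow decay; noise and PSCs off
  sim <- simulate_mapping_experiment(
    n_targets = 6, n_reps = 2, connection_prob = 0,
    photo = photocurrent_population(
      p = 1, kinetics_ranges = list(tau_o = c(3, 3), tau_r = c(40, 40),
                                    O_inf = c(1, 1), R_inf = c(0.8, 0.8))),
    psc = psc_params(spont_rate_hz = 0), noise_sd = 0, seed = 39)
  pre <- -sim$raw[-1, 1:100]   # pre-stimulus context, inward-positive
  prev_active <- sim$truth$A[-nrow(sim$raw)] > 0
  expect_true(all(rowSums(pre)[prev_active] > 0))
  # and the tail decays within the context window
  decaying <- pre[prev_active, , drop = FALSE]
  expect_true(all(decaying[, 1] >= decaying[, 100]))
})

test_that("ensemble photocurrents add linearly over stimulated targets", {
  sim <- simulate_mapping_experiment(
    n_targets = 20, n_reps = 1, ensemble_size = 10, connection_prob = 0,
    photo = photocurrent_population(p = 0.5, sigma_A = 0),
    psc = psc_params(spont_rate_hz = 0), noise_sd = 0, seed = 40)
  I_max <- sim$metadata$max_power_mW
  for (k in seq_along(sim$metadata$targets)) {
    tg <- sim$metadata$targets[[k]]
    expected <- sum(sim$truth$mu[tg] * sim$metadata$powers_mW[k] / I_max)
    expect_equal(sim$truth$A[k], expected, tolerance = 1e-9)
  }
})

test_that("hybrid field follows the spatial-sigmoidal mean", {
  f <- hybrid_field(c_um = c(0, 0, 0), Sigma = diag(c(100, 100, 100)),
                    phi0 = 1000, phi1 = 40, sigma_A = 0)
  # at the cell and the half-power point: phi0 / 2
  expect_equal(hybrid_mean_amplitude(c(0, 0, 0), 40, f), 500)
  # printed example: offset (10,0,0), Sigma = diag(100) -> e^-1 factor
  expect_equal(hybrid_mean_amplitude(c(10, 0, 0), 40, f), 1000 * exp(-1) * 0.5,
               tolerance = 1e-9)
  expect_equal(round(hybrid_mean_amplitude(c(10, 0, 0), 40, f), 1), 183.9)
  # vanishing far away
  expect_lt(hybrid_mean_amplitude(c(500, 0, 0), 60, f), 1e-12)
})

test_that("hybrid injection adds inward-negative scaled waveforms", {
  set.seed(41)
  raw <- matrix(0, 4, 900)
  md <- stimulus_metadata(rep(60, 4), 60, 1:4,
                          target_locations_um = rbind(c(0, 0, 0), c(5, 0, 0),
                                                      c(60, 0, 0), c(500, 0, 0)))
  w <- window_spec(101, 100, n_samples = 900)
  f <- hybrid_field(Sigma = diag(c(900, 900, 900)), phi0 = 400, phi1 = 30,
                    sigma_A = 0)
  kin <- opsin_kinetics(t_on = 5, t_off = 10)
  inj <- inject_hybrid(raw, md, f, kin, w)
  expect_true(all(inj$raw <= 0))            # inward-negative contamination
  expect_true(inj$A[1] > inj$A[3])          # decays with distance
  expect_lt(inj$A[4], 1e-6)
  expect_equal(inj$A, inj$mu, tolerance = 1e-9)  # sigma_A = 0
})
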