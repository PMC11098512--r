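test_that("per_target_responses averages charges per target and power", {
  w <- window_spec(t1 = 1, stim_duration_samples = 10, t2 = 10, t3 = 11,
                   response_window_ms = 1, n_samples = 40)
  # two trials of target 1 at one power with charges 10 and 20 pA*ms
  tr <- rbind(rep(10 / (20 * 0.05), 40), rep(20 / (20 * 0.05), 40))
  md <- stimulus_metadata(c(30, 30), 30, c(1L, 1L))
  resp <- per_target_responses(tr, md, w)
  expect_equal(unname(resp$mean_charge[1, 1]), 15)
  expect_equal(unname(per_target_responses(matrix(0, 2, 40), md, w)$mean_charge[1, 1]), 0)
  # permutation invariance of the average
  set.seed(51)
  tr2 <- matrix(runif(5 * 40), 5, 40)
  md2 <- stimulus_metadata(rep(30, 5), 30, rep(1L, 5))
  r1 <- per_target_responses(tr2, md2, w)$mean_charge
  perm <- sample(5)
  r2 <- per_target_responses(tr2[perm, ], stimulus_metadata(rep(30, 5), 30,
                                                            rep(1L, 5)), w)$mean_charge
  expect_equal(r1, r2)
  expect_error(per_target_responses(tr, stimulus_metadata(30, 30, list(c(1L, 2L))),
                                    w), "single-target")
})

test_that("detect_connections finds obvious connections and nothing in silence", {
  w <- window_spec(t1 = 101, stim_duration_samples = 100, n_samples = 900)
  md <- stimulus_metadata(rep(60, 16), 60, rep(1:8, 2))
  silent <- matrix(0, 16, 900)
  est0 <- detect_connections(silent, md, w, noise_sd = 1)
  expect_equal(sum(est0$detected), 0L)
  expect_error(detect_connections(silent, md, w, k_sigma = 0), "k_sigma")
  # target 1 responds at 100x the noise floor on every trial
  resp <- silent
  resp[vapply(md$targets, `[[`, 1L, 1L) == 1L, 150:400] <- 20
  est <- detect_connections(resp, md, w, noise_sd = 1)
  expect_true(est$detected[1])
  expect_false(any(est$detected[2:8]))
  expect_equal(est$weights[1], sum(rep(20, 251)) * 0.05, tolerance = 1e-6)
})

test_that("false-positive rate is controlled without photocurrents", {
  fp <- 0
  unconn <- 0
  for (s in 1:10) {
    sim <- simulate_mapping_experiment(n_targets = 40, n_reps = 15,
                                       photo = photocurrent_population(p = 0),
                                       seed = 600 + s)
    est <- detect_connections(-sim$raw, sim$metadata, sim$window,
                              k_sigma = 4)
    fp <- fp + sum(est$detected & !sim$truth$connected)
    unconn <- unconn + sum(!sim$truth$connected)
  }
  expect_lt(fp / unconn, 0.02)
})

test_that("connection_waveforms matches decoupled and shrinkage limits", {
  set.seed(52)
  C <- matrix(rnorm(3 * 20), 3, 20)
  W <- connection_waveforms(C, diag(3), lambda_ridge = 0)
  expect_equal(W, pmax(C, 0), tolerance = 1e-8)
  W2 <- connection_waveforms(C, diag(3), lambda_ridge = 1e8)
  expect_lt(max(W2), 1e-6)
  expect_warning(connection_waveforms(C, rbind(c(1, 1, 0), 0), 1), "zero")
})

test_that("connection_waveforms matches the brute-force QP oracle", {
  set.seed(53)
  for (i in 1:20) {
    cells <- sample(2:4, 1)
    trials <- 6
    Tn <- 8
    Lambda <- matrix(rbinom(cells * trials, 1, 0.5), cells, trials)
    Lambda[rowSums(Lambda) == 0, 1] <- 1
    C <- matrix(rnorm(trials * Tn, 1), trials, Tn)
    lam <- sample(c(0, 0.5, 2), 1)
    W <- connection_waveforms(C, Lambda, lam)
    for (t in seq_len(Tn)) {
      want <- oracle_nnls_ridge(t(Lambda), C[, t], lam)
      expect_equal(W[, t], want, tolerance = 1e-6)
    }
  }
})

test_that("spike matrix surrogate thresholds stimulated trials", {
  md <- stimulus_metadata(rep(60, 4), 60, list(1L, 2L, c(1L, 2L), 1L))
  L <- spike_matrix_surrogate(md, charges = c(10, 1, 10, 1), floor = 5,
                              n_targets = 2)
  expect_equal(L, rbind(c(1, 0, 1, 0), c(0, 0, 1, 0)))
})

test_that("representative-trace selection ranks by the right scores", {
  w <- window_spec(t1 = 101, stim_duration_samples = 100, n_samples = 900)
  artifact <- matrix(0, 6, 900)
  artifact[1:3, 101:200] <- c(300, 200, 100)  # recycled by row
  demixed <- matrix(0, 6, 900)
  demixed[4:6, 170:300] <- 50                 # inside the 3-12 ms latency window
  sel <- select_representative_traces(list(artifact = artifact), demixed, w,
                                      n = 3)
  expect_setequal(sel$photocurrent, 1:3)
  expect_setequal(sel$synaptic, 4:6)
  expect_length(intersect(sel$photocurrent, sel$synaptic), 0)
  expect_warning(sel_all <- select_representative_traces(
    list(artifact = artifact), demixed, w, n = 10), "truncat")
  expect_setequal(sel_all$photocurrent, 1:6)
})

test_that("evaluation scores weights and detections against truth", {
  truth <- list(connected = c(FALSE, TRUE, TRUE), weights = c(0, 1, 2))
  perfect <- list(weights = c(0, 1, 2), detected = c(FALSE, TRUE, TRUE))
  r <- evaluate_connectivity(truth, perfect)
  expect_equal(r$r_squared, 1)
  expect_equal(r$false_positives + r$false_negatives, 0)

  est <- list(weights = c(0, 1, 1), detected = c(FALSE, TRUE, TRUE))
  # raw comparison: SS_res = 1, SS_tot = 2
  expect_equal(evaluate_connectivity(truth, est, gain_correct = FALSE)$r_squared,
               0.5)
  # gain-corrected: g = 3/2, SS_res = 0.5 (computed by hand)
  g <- sum(c(0, 1, 2) * c(0, 1, 1)) / sum(c(0, 1, 1)^2)
  r2 <- 1 - sum((c(0, 1, 2) - g * c(0, 1, 1))^2) / 2
  expect_equal(evaluate_connectivity(truth, est)$r_squared, r2)
  expect_equal(r2, 0.75)

  zero <- list(weights = c(0, 0, 0), detected = rep(FALSE, 3))
  expect_lte(evaluate_connectivity(truth, zero)$r_squared, 0)
})

test_that("evaluation is invariant to permutation and positive rescaling", {
  set.seed(54)
  truth <- list(connected = rbinom(20, 1, 0.3) == 1, weights = numeric(20))
  truth$weights[truth$connected] <- rgamma(sum(truth$connected), 2, scale = 25)
  est <- list(weights = truth$weights * 7 + rnorm(20, sd = 0.1),
              detected = truth$weights > 0)
  r1 <- evaluate_connectivity(truth, est)
  est2 <- list(weights = est$weights * 3.3, detected = est$detected)
  expect_equal(evaluate_connectivity(truth, est2)$r_squared, r1$r_squared,
               tolerance = 1e-9)
  perm <- sample(20)
  r3 <- evaluate_connectivity(list(connected = truth$connected[perm],
                                   weights = truth$weights[perm]),
                              list(weights = est$weights[perm],
                                   detected = est$detected[perm]))
  expect_equal(r3$r_squared, r1$r_squared, tolerance = 1e-12)
})

test_that("effective response window truncates at the ISI", {
  w <- window_spec(t1 = 101, stim_duration_samples = 100, n_samples = 900)
  md <- stimulus_metadata(rep(60, 3), 60, 1:3,
                          trial_times_s = c(0, 0.030, 0.060))
  expect_equal(effective_response_window(w, md), 600L)
  md2 <- stimulus_metadata(rep(60, 3), 60, 1:3)
  expect_equal(effective_response_window(w, md2), 700L)
})
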