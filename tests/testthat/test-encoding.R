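test_that("basis responses evaluate cos^7 of the wrapped offset", {
  b <- basis_set()
  r0 <- basis_responses(stimulus_orientations()[3], b)
  expect_equal(r0[3], 1)                       # zero offset
  # one grid step away: cos^7(22.5 deg) = 0.5745 (4 d.p.)
  expect_equal(round(r0[2], 4), 0.5745)
  expect_equal(round(r0[4], 4), 0.5745)
  # 90 degrees away responds 0 (wrap makes -78.75 vs 11.25 a 90 offset)
  expect_equal(basis_responses(11.25, b)[1], 0, tolerance = 1e-15)
  expect_true(all(basis_responses(runif(1, -90, 90), b) >= 0))
})

test_that("weight estimation is exact least squares with rank
           diagnostics", {
  set.seed(40)
  W_true <- matrix(rnorm(12 * 8), 12, 8)
  th <- rep(stimulus_orientations(), 3)
  C1 <- design_matrix(th)
  B1 <- W_true %*% C1
  expect_equal(estimate_weights(B1, C1), W_true, tolerance = 1e-10)
  # residual orthogonal to the design rows, also with noise
  B1n <- B1 + matrix(rnorm(length(B1)), nrow(B1))
  Wn <- estimate_weights(B1n, C1)
  expect_lt(max(abs((B1n - Wn %*% C1) %*% t(C1))), 1e-8)
  # only 4 distinct orientations -> C1 C1' singular
  C4 <- design_matrix(rep(stimulus_orientations()[1:4], 2))
  expect_error(estimate_weights(B1[, 1:8], C4), "rank deficient")
  # unbiasedness over noisy replicates, judged against the analytic
  # sampling error of the mean (the cos^7 design is ill-conditioned, so
  # per-entry noise amplification varies strongly across channels)
  n_rep <- 200; noise_sd <- 1
  reps <- replicate(n_rep, {
    estimate_weights(B1 + matrix(rnorm(length(B1), sd = noise_sd),
                                 nrow(B1)), C1)
  })
  bias <- apply(reps, c(1, 2), mean) - W_true
  se <- noise_sd * sqrt(diag(solve(tcrossprod(C1)))) / sqrt(n_rep)
  expect_true(all(abs(bias) < 5 * rep(se, each = nrow(W_true))))
})

test_that("inversion recovers channel responses on consistent data", {
  set.seed(41)
  W <- matrix(rnorm(10 * 8), 10, 8)
  C_true <- design_matrix(runif(5, -90, 90))
  expect_equal(invert_to_ctf(W, W %*% C_true), C_true,
               tolerance = 1e-10)
  expect_equal(dim(invert_to_ctf(W, W %*% C_true)), c(8, 5))
  expect_error(invert_to_ctf(W[1:6, ], (W %*% C_true)[1:6, ]),
               "singular")
})

test_that("baseline correction centers each observation and is
           idempotent", {
  set.seed(42)
  M <- matrix(rnorm(8 * 4), 8, 4)
  Mc <- baseline_correct(M)
  expect_equal(colSums(Mc), rep(0, 4), tolerance = 1e-12)
  expect_equal(baseline_correct(Mc), Mc)
  expect_equal(baseline_correct(matrix(3, 8, 2)),
               matrix(0, 8, 2))
})

test_that("alignment shifts each orientation's profile to a common
           center", {
  C <- design_matrix(stimulus_orientations())
  prof <- align_and_average(C)
  # basis-shaped profiles at each orientation align to the basis profile
  expect_equal(max(prof$responses), prof$responses[prof$offsets == 0])
  expect_equal(prof$responses[prof$offsets == 0], 1)
  expect_equal(prof$responses[prof$offsets == -22.5],
               cos(22.5 * pi / 180)^7)
  # a single nonzero profile contributes 1/8 of its values
  C1 <- matrix(0, 8, 8); C1[, 3] <- basis_responses(
    stimulus_orientations()[3])
  prof1 <- align_and_average(C1)
  expect_equal(prof1$responses[prof1$offsets == 0], 1 / 8)
  expect_error(align_and_average(C[, 1:7]), "orientation bin")
})

test_that("ctf_slope equals an independent least-squares regression on
           the folded axis", {
  folded <- c(-90, -67.5, -45, -22.5, 0, -22.5, -45, -67.5)
  set.seed(43)
  for (i in 1:5) {
    resp <- rnorm(8)
    oracle <- unname(coef(lm(resp ~ folded))[2])
    expect_equal(ctf_slope(resp), oracle, tolerance = 1e-12)
  }
  expect_equal(ctf_slope(rep(0.7, 8)), 0, tolerance = 1e-15)
  # trough-at-center profile is the exact negative of the peaked case
  peaked <- align_and_average(design_matrix(stimulus_orientations()))
  expect_equal(ctf_slope(-peaked$responses), -ctf_slope(peaked))
  expect_gt(ctf_slope(peaked), 0)
  # invariance to additive constants; linear in amplitude
  expect_equal(ctf_slope(peaked$responses + 5), ctf_slope(peaked),
               tolerance = 1e-12)
  expect_equal(ctf_slope(3 * peaked$responses), 3 * ctf_slope(peaked),
               tolerance = 1e-12)
})

test_that("noiseless stable data close the IEM loop at the ideal basis
           slope", {
  ep <- make_epochs(n_trials = 48, noise_sd = 0, seed = 44)
  post <- ep$times[ep$times >= 0]
  iem <- run_iem(ep, n_iterations = 2, seed = 45, times = post)
  ideal <- ctf_slope(ideal_basis_profile())
  expect_equal(iem$slope, rep(ideal, length(post)), tolerance = 1e-10)
  # determinism under the seed
  iem2 <- run_iem(ep, n_iterations = 2, seed = 45, times = post)
  expect_identical(iem$slope, iem2$slope)
})

test_that("shuffled orientation labels drive the mean slope to zero", {
  ep <- make_epochs(n_trials = 96, noise_sd = 1, seed = 46)
  set.seed(47)
  slopes <- vapply(1:30, function(i) {
    eps <- ep
    eps$trial_table$mean_orientation_bin <-
      sample(eps$trial_table$mean_orientation_bin)
    mean(run_iem(eps, n_iterations = 2, seed = i,
                 times = c(0.1, 0.2))$slope)
  }, numeric(1))
  expect_lt(abs(mean(slopes)), 2 * sd(slopes) / sqrt(length(slopes)) + 1e-4)
})

test_that("cross-condition generalization matches construction at the
           lambda extremes", {
  cfg <- sim_config(n_trials_so = 48, n_trials_vo = 48,
                    n_electrodes = 12, sampling_rate = 100,
                    epoch_window = c(-0.05, 0.15), noise_sd = 0,
                    lambda = 1, seed = 48)
  ws <- weight_schedule(cfg)
  so <- simulate_epochs(balanced_stimuli(6, "SO", 1, seed = 49), cfg,
                        weights = ws)
  vo1 <- simulate_epochs(balanced_stimuli(6, "VO", 1, seed = 50), cfg,
                         weights = ws)
  post <- so$times[so$times >= 0]
  ideal <- ctf_slope(ideal_basis_profile())
  cc1 <- cross_condition_iem(so, vo1, n_iterations = 2, seed = 51,
                             times = post)
  # lambda = 1: VO channel input is the basis at the mean; slope = ideal
  expect_equal(cc1$slope, rep(ideal, length(post)), tolerance = 1e-10)
  # lambda = 0 with +/-10/30 offsets: mixture profile is flatter than
  # the basis but still tuned to the mean
  cfg0 <- cfg; cfg0$lambda <- 0
  vo0 <- simulate_epochs(balanced_stimuli(6, "VO", 1, seed = 50), cfg0,
                         weights = ws)
  cc0 <- cross_condition_iem(so, vo0, n_iterations = 2, seed = 51,
                             times = post)
  expect_true(all(cc0$slope > 0))
  expect_true(all(cc0$slope < cc1$slope))
  # electrode mismatch is refused
  vo_bad <- vo1; vo_bad$electrode_labels <- rev(vo_bad$electrode_labels)
  expect_error(cross_condition_iem(so, vo_bad, n_iterations = 1),
               "electrode")
})

test_that("cross-condition slope increases with the ensemble weight
           lambda", {
  lams <- seq(0, 1, by = 0.25)
  cfg <- sim_config(n_trials_so = 48, n_trials_vo = 48,
                    n_electrodes = 12, sampling_rate = 100,
                    epoch_window = c(-0.02, 0.03), noise_sd = 1,
                    seed = 52)
  slopes <- vapply(seq_along(lams), function(j) {
    mean(vapply(1:20, function(r) {       # 20 replicates per lambda
      cfgj <- cfg; cfgj$lambda <- lams[j]
      cfgj$seed <- 1000 + r
      ws <- weight_schedule(cfgj)
      so <- simulate_epochs(balanced_stimuli(6, "SO", 1,
                                             seed = 2000 + r),
                            cfgj, weights = ws)
      vo <- simulate_epochs(balanced_stimuli(6, "VO", 1,
                                             seed = 3000 + r),
                            cfgj, weights = ws)
      mean(cross_condition_iem(so, vo, n_iterations = 1,
                               seed = r, times = 0.02)$slope)
    }, numeric(1)))
  }, numeric(1))
  expect_gt(cor(lams, slopes, method = "spearman"), 0)
  expect_gt(slopes[5], slopes[1])
})
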