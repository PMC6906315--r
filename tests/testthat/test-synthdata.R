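test_that("stimulus sets obey the SO/VO construction rules", {
  so <- stimulus_set(33.75, "SO", 1)
  expect_equal(so$item_orientations, rep(33.75, 20))
  vo <- stimulus_set(11.25, "VO", 1)
  expect_equal(sort(unique(vo$item_orientations)),
               c(-18.75, 1.25, 21.25, 41.25))
  expect_equal(unname(table(vo$item_orientations)), rep(5L, 4),
               ignore_attr = TRUE)
  # the mean orientation itself is never shown in VO
  expect_false(11.25 %in% vo$item_orientations)
  vo2 <- stimulus_set(-33.75, "VO", 2)
  expect_equal(sort(orientation_diff(unique(vo2$item_orientations),
                                     -33.75)),
               c(-22.5, -7.5, 7.5, 22.5))
  expect_error(stimulus_set(0, "VO", 3), "experiment")
})

test_that("generate_stimuli draws means from the 8-orientation grid,
           reproducibly", {
  st <- generate_stimuli(200, "VO", 1, seed = 11)
  means <- vapply(st, `[[`, numeric(1), "mean_orientation")
  expect_true(all(means %in% stimulus_orientations()))
  st2 <- generate_stimuli(200, "VO", 1, seed = 11)
  expect_identical(st, st2)
  st3 <- generate_stimuli(200, "VO", 1, seed = 12)
  expect_false(identical(attr(st, "mean_bin"), attr(st3, "mean_bin")))
})

test_that("noiseless stable epochs equal the exact forward model", {
  ws_cfg <- sim_config(n_trials_so = 8, n_electrodes = 10,
                       sampling_rate = 100, epoch_window = c(-0.05, 0.1),
                       noise_sd = 0, seed = 3)
  ws <- weight_schedule(ws_cfg)
  stim <- generate_stimuli(8, "SO", 1, seed = 4)
  ep <- simulate_epochs(stim, ws_cfg, weights = ws)
  C <- design_matrix(vapply(stim, `[[`, numeric(1), "mean_orientation"))
  expected <- t(ws$W_stable %*% C)                  # trials x electrodes
  for (s in which(ep$times >= 0))
    expect_equal(ep$data[, , s], expected, tolerance = 1e-12)
  # pre-onset: no tuning contribution (pure noise = 0 here)
  for (s in which(ep$times < 0))
    expect_equal(max(abs(ep$data[, , s])), 0)
})

test_that("a lambda=1 VO trial carries the same channel input as an SO
           trial at the mean orientation", {
  cfg <- sim_config(n_trials_so = 1, n_electrodes = 9,
                    sampling_rate = 100, epoch_window = c(-0.02, 0.05),
                    noise_sd = 0, lambda = 1, seed = 5)
  ws <- weight_schedule(cfg)
  vo <- simulate_epochs(list(stimulus_set(11.25, "VO", 1)), cfg,
                        weights = ws)
  so <- simulate_epochs(list(stimulus_set(11.25, "SO", 1)), cfg,
                        weights = ws)
  expect_equal(vo$data, so$data, tolerance = 1e-12)
})

test_that("dynamic-regime weight segments are statistically independent", {
  cfg <- sim_config(n_trials_so = 1, n_electrodes = 10,
                    sampling_rate = 100, epoch_window = c(-0.1, 0.25),
                    coding_regime = "dynamic", segment_len_s = 0.1,
                    seed = 1)
  cors <- vapply(seq_len(150), function(i) {
    ws <- weight_schedule(cfg, seed = i)
    cor(as.vector(ws$W_segments[[1]]), as.vector(ws$W_segments[[2]]))
  }, numeric(1))
  expect_lt(abs(mean(cors)), 0.03)   # Monte-Carlo over 150 draws
})

test_that("old/new observer is deterministic at kappa=Inf and tuned to
           the probe design", {
  # w = 0, no noise, SO, probe at the memorized orientation -> "old"
  stim <- replicate(40, stimulus_set(-56.25, "SO", 1), simplify = FALSE)
  tab <- simulate_oldnew_behavior(stim, w = 0, kappa = Inf, seed = 7)
  at_item <- tab$probe_offset_deg == 0
  expect_true(all(tab$response[at_item] == "old"))
  # probe offsets follow the VO design with equal probabilities
  vstim <- generate_stimuli(4000, "VO", 1, seed = 8)
  vtab <- simulate_oldnew_behavior(vstim, w = 0.5, kappa = 8, seed = 9)
  expect_true(all(vtab$probe_offset_deg %in% probe_offsets_oldnew("VO")))
  tallies <- table(vtab$probe_offset_deg)
  expect_equal(length(tallies), 18)
  expect_true(all(abs(tallies / nrow(vtab) - 1 / 18) < 0.02))
  # same seed -> identical tables
  expect_identical(vtab, simulate_oldnew_behavior(vstim, w = 0.5,
                                                  kappa = 8, seed = 9))
})

test_that("full ensemble reliance makes P(old) peak at the mean and
           decay with probe offset", {
  vstim <- generate_stimuli(6000, "VO", 1, seed = 10)
  tab <- simulate_oldnew_behavior(vstim, w = 1, kappa = 12, seed = 11)
  curve <- oldnew_tuning_curve(tab)
  agg <- tapply(curve$prop_old, abs(curve$probe_offset_deg), mean)
  offs <- as.numeric(names(agg))
  expect_equal(names(which.max(agg)), "0")
  expect_lt(cor(offs, as.vector(agg), method = "spearman"), -0.8)
})

test_that("estimation responses carry the stated toward-mean bias", {
  stim <- generate_stimuli(8000, "VO", 2, seed = 12)
  # w = 0 and no noise: all response errors are exactly 0
  t0 <- simulate_estimation_behavior(stim[1:50], w = 0, kappa = Inf,
                                     seed = 13)
  expect_equal(t0$response_error_deg, rep(0, 50))
  # expected error is -w * target_offset
  tb <- simulate_estimation_behavior(stim, w = 0.5, kappa = 20, seed = 14)
  m225 <- mean(tb$response_error_deg[tb$target_offset_deg == 22.5])
  expect_equal(m225, -11.25, tolerance = 0.6)
  expect_identical(tb, simulate_estimation_behavior(stim, w = 0.5,
                                                    kappa = 20,
                                                    seed = 14))
  expect_error(simulate_estimation_behavior(
    list(stimulus_set(0, "SO", 2)), w = 0.5), "VO")
})

test_that("epoch sets round-trip through the on-disk directory format", {
  ep <- make_epochs(n_trials = 10, noise_sd = 1, seed = 20)
  dir <- tempfile("epochs_")
  write_epochs(ep, dir)
  back <- read_epochs(dir)
  expect_equal(back$data, ep$data)
  expect_equal(back$times, ep$times)
  expect_equal(back$trial_table$mean_orientation_bin,
               ep$trial_table$mean_orientation_bin)
  unlink(dir, recursive = TRUE)
})

test_that("epoch-set validation rejects malformed containers", {
  ep <- make_epochs(n_trials = 6, seed = 21)
  expect_error(epoch_set(ep$data, ep$times, ep$sampling_rate,
                         ep$electrode_labels,
                         ep$trial_table[1:3, ]), "trial table")
  expect_error(epoch_set(ep$data, ep$times, ep$sampling_rate,
                         rep("E01", 12), ep$trial_table), "unique")
  expect_error(epoch_set(ep$data, rev(ep$times), ep$sampling_rate,
                         ep$electrode_labels, ep$trial_table),
               "increasing")
})
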