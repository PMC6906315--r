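# Small synthetic fixtures shared across test files. All data are built
# in code; sizes are kept modest so the default run stays fast.

# Stimulus list with an equal number of trials per orientation bin
# (decoding fixtures need every bin to cover all folds).
balanced_stimuli <- function(n_per_bin, condition = "SO",
                             experiment = 1, seed = 1) {
  oris <- rep(stimulus_orientations(), each = n_per_bin)
  set.seed(seed)
  lapply(sample(oris), stimulus_set, condition = condition,
         experiment = experiment)
}

# One subject's epochs with balanced orientation counts.
make_epochs <- function(n_trials = 48, condition = "SO", experiment = 1,
                        n_electrodes = 12, sampling_rate = 100,
                        epoch_window = c(-0.1, 0.3), noise_sd = 0,
                        regime = "stable", lambda = 0.5, seed = 1,
                        weights = NULL) {
  cfg <- sim_config(n_trials_so = n_trials, n_trials_vo = n_trials,
                    n_electrodes = n_electrodes,
                    sampling_rate = sampling_rate,
                    epoch_window = epoch_window, noise_sd = noise_sd,
                    coding_regime = regime, lambda = lambda,
                    experiment = experiment, seed = seed)
  stim <- if (n_trials %% 8 == 0)
    balanced_stimuli(n_trials / 8, condition, experiment,
                     seed = seed + 1000)
  else generate_stimuli(n_trials, condition, experiment,
                        seed = seed + 1000)
  simulate_epochs(stim, cfg, weights = weights)
}

# Preprocess like the pipeline: 51-sample boxcar then 100 Hz.
prep_decode <- function(epochs) downsample(moving_average(epochs), 100)

# A study-structured subject (500 Hz, smoothing, 100 Hz decoding grid).
make_study_subject <- function(i, regime = "stable", n_trials = 96,
                               noise_sd = 2, window = c(-0.2, 0.8)) {
  cfg <- sim_config(n_trials_so = n_trials, n_trials_vo = n_trials,
                    n_electrodes = 28, sampling_rate = 500,
                    epoch_window = window, noise_sd = noise_sd,
                    coding_regime = regime, seed = 100 + i)
  stim <- balanced_stimuli(n_trials / 8, "SO", 1, seed = 200 + i)
  prep_decode(simulate_epochs(stim, cfg))
}

# Ideal aligned CTF profile of the basis and its slope (the noiseless
# closed-loop target).
ideal_basis_profile <- function() {
  align_and_average(design_matrix(stimulus_orientations()))
}

# Balanced behavioral table at the 19 VO probe offsets with k_i "old"
# responses drawn from a known Weibull observer.
weibull_observer_table <- function(alpha, beta, gamma, delta,
                                   n_per_level = 50, seed = 1) {
  offs <- probe_offsets_oldnew("VO")
  set.seed(seed)
  do.call(rbind, lapply(offs, function(o) {
    p <- weibull_cdf(1 - abs(o) / 90, alpha, beta, gamma, delta)
    k <- stats::rbinom(1, n_per_level, p)
    data.frame(
      probe_offset_deg = rep(o, n_per_level),
      response = c(rep("old", k), rep("new", n_per_level - k)),
      condition = "VO", stringsAsFactors = FALSE)
  }))
}
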