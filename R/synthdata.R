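## Forward-model synthetic data generator. Every downstream stage of the
## pipeline is exercised on data from this module: epoched multichannel
## signals built as weighted sums of orientation-channel responses plus
## Gaussian noise, plus behavioral tables for both tasks.

#' Build a stimulus set
#'
#' A display of 20 oriented bars. In the same-orientation (SO) condition
#' all 20 bars share the mean orientation; in the varied-orientation (VO)
#' condition the bars take four offsets around the mean (five bars each)
#' and the mean orientation itself is never shown. Offsets are
#' \eqn{\pm 10, \pm 30} degrees in experiment 1 and
#' \eqn{\pm 7.5, \pm 22.5} degrees in experiment 2.
#'
#' @param mean_orientation Mean orientation in degrees.
#' @param condition `"SO"` or `"VO"`.
#' @param experiment 1 or 2 (sets the VO offsets).
#' @return Object of class `stimulus_set` with fields `mean_orientation`,
#'   `condition`, `experiment`, `item_orientations` (length 20).
#' @export
stimulus_set <- function(mean_orientation, condition = c("SO", "VO"),
                         experiment = 1) {
  condition <- match.arg(condition)
  if (!experiment %in% c(1, 2)) stop("unknown experiment: ", experiment)
  mean_orientation <- wrap_orientation(mean_orientation)
  items <- if (condition == "SO") {
    rep(mean_orientation, 20)
  } else {
    rep(wrap_orientation(mean_orientation + vo_offsets(experiment)),
        each = 5)
  }
  structure(list(mean_orientation = mean_orientation,
                 condition = condition, experiment = experiment,
                 item_orientations = items),
            class = "stimulus_set")
}

#' VO item offsets for an experiment
#' @param experiment 1 or 2.
#' @return The four item offsets from the mean, in degrees.
#' @export
vo_offsets <- function(experiment) {
  switch(as.character(experiment),
         "1" = c(-30, -10, 10, 30),
         "2" = c(-22.5, -7.5, 7.5, 22.5),
         stop("unknown experiment: ", experiment))
}

#' Generate trial stimuli
#'
#' Each trial's mean orientation is drawn uniformly from the eight
#' stimulus orientations; items follow the SO/VO construction rules.
#'
#' @param n_trials Number of trials.
#' @param condition `"SO"` or `"VO"`.
#' @param experiment 1 or 2.
#' @param seed Integer seed.
#' @return List of [stimulus_set()]s with attribute `mean_bin` (1..8).
#' @export
generate_stimuli <- function(n_trials, condition = c("SO", "VO"),
                             experiment = 1, seed = 1) {
  condition <- match.arg(condition)
  stopifnot(n_trials >= 1)
  set.seed(seed)
  bins <- sample.int(8, n_trials, replace = TRUE)
  oris <- stimulus_orientations()[bins]
  out <- lapply(oris, stimulus_set, condition = condition,
                experiment = experiment)
  attr(out, "mean_bin") <- bins
  out
}

#' Simulation configuration
#'
#' Parameters of the forward model. Defaults state the emulated world:
#' 28 electrodes and 500 Hz native sampling as recorded, epochs from
#' -200 ms to 1600 ms around stimulus onset, i.i.d. Gaussian sensor noise
#' (sd 2, a moderate trial-level SNR for this signal scale), a stable
#' weight regime, 100 ms weight segments in the dynamic regime, and a VO
#' ensemble weight `lambda` of 0.5 (equal mix of mean-orientation and
#' item-average channel input; the generative VO model is this package's
#' construct, not an empirical claim).
#'
#' @param n_trials_so,n_trials_vo Trials per condition.
#' @param n_electrodes Electrode count (>= 8 so least squares is posed).
#' @param sampling_rate Hz.
#' @param epoch_window `c(start, end)` in seconds; must cover onset t = 0.
#' @param noise_sd Sensor noise SD (signal units), >= 0.
#' @param coding_regime `"stable"`, `"dynamic"` or `"mixed"`.
#' @param segment_len_s Weight-redraw granularity in the dynamic regime.
#' @param lambda VO ensemble weight in `[0, 1]`: channel input is
#'   `lambda * basis(mean) + (1 - lambda) * mean over item basis`.
#' @param bias_w Behavioral bias toward the mean, in `[0, 1]`.
#' @param response_kappa Concentration of behavioral response noise
#'   (doubled-angle von Mises).
#' @param ar1 Optional AR(1) coefficient for temporally correlated noise;
#'   default 0 (off).
#' @param experiment 1 or 2.
#' @param seed Integer master seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_trials_so = 1024, n_trials_vo = 288,
                       n_electrodes = 28, sampling_rate = 500,
                       epoch_window = c(-0.2, 1.6), noise_sd = 2,
                       coding_regime = c("stable", "dynamic", "mixed"),
                       segment_len_s = 0.1, lambda = 0.5, bias_w = 0.5,
                       response_kappa = 8, ar1 = 0, experiment = 1,
                       seed = 1) {
  coding_regime <- match.arg(coding_regime)
  stopifnot(lambda >= 0, lambda <= 1, bias_w >= 0, bias_w <= 1,
            noise_sd >= 0, sampling_rate > 0, segment_len_s > 0,
            n_electrodes >= 8, abs(ar1) < 1)
  if (epoch_window[1] > 0 || epoch_window[2] <= epoch_window[1])
    stop("epoch window must cover stimulus onset at t = 0")
  structure(list(n_trials_so = n_trials_so, n_trials_vo = n_trials_vo,
                 n_electrodes = n_electrodes,
                 sampling_rate = sampling_rate,
                 epoch_window = epoch_window, noise_sd = noise_sd,
                 coding_regime = coding_regime,
                 segment_len_s = segment_len_s, lambda = lambda,
                 bias_w = bias_w, response_kappa = response_kappa,
                 ar1 = ar1, experiment = experiment, seed = seed),
            class = "sim_config")
}

#' Construct an epoch set
#'
#' Container for epoched multichannel signals: a trials x electrodes x
#' samples array with a uniform time axis and a per-trial label table.
#'
#' @param data 3-d array, trials x electrodes x samples.
#' @param times Sample times in seconds relative to stimulus onset.
#' @param sampling_rate Hz.
#' @param electrode_labels Unique electrode names.
#' @param trial_table Data frame with one row per trial; must contain a
#'   `mean_orientation_bin` column (1..8).
#' @return Object of class `epoch_set`.
#' @export
epoch_set <- function(data, times, sampling_rate, electrode_labels,
                      trial_table) {
  x <- structure(list(data = data, times = times,
                      sampling_rate = sampling_rate,
                      electrode_labels = electrode_labels,
                      trial_table = trial_table),
                 class = "epoch_set")
  .validate_epochs(x)
  x
}

.validate_epochs <- function(x) {
  stopifnot(inherits(x, "epoch_set") || is.list(x))
  d <- dim(x$data)
  if (length(d) != 3) stop("epoch data must be trials x electrodes x samples")
  if (nrow(x$trial_table) != d[1])
    stop("trial table length (", nrow(x$trial_table),
         ") does not match trial dimension (", d[1], ")")
  if (length(x$electrode_labels) != d[2])
    stop("electrode labels do not match electrode dimension")
  if (anyDuplicated(x$electrode_labels))
    stop("electrode labels must be unique")
  if (length(x$times) != d[3])
    stop("time axis does not match sample dimension")
  dt <- diff(x$times)
  if (any(dt <= 0) || max(abs(dt - 1 / x$sampling_rate)) > 1e-9)
    stop("times must be strictly increasing and uniform at sampling_rate")
  invisible(TRUE)
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat("Epoch set: ", d[1], " trials x ", d[2], " electrodes x ", d[3],
      " samples @ ", x$sampling_rate, " Hz (",
      format(min(x$times)), "..", format(max(x$times)), " s)\n", sep = "")
  if ("condition" %in% names(x$trial_table))
    print(table(x$trial_table$condition))
  invisible(x)
}

#' Draw a subject's true weight schedule
#'
#' The forward model's electrode-by-channel weights, entries i.i.d.
#' standard normal. In the stable regime one matrix holds for the whole
#' epoch; in the dynamic regime an independent matrix is drawn for every
#' post-onset segment of `segment_len_s`; `mixed` averages a persistent
#' and a per-segment component, each scaled by \eqn{1/\sqrt 2}.
#'
#' @param cfg A [sim_config()] (regime, electrode count, epoch window,
#'   segment length).
#' @param seed Seed for the draw; default `cfg$seed`.
#' @param basis Channel [basis_set()].
#' @return Object of class `weight_schedule`.
#' @export
weight_schedule <- function(cfg, seed = cfg$seed, basis = basis_set()) {
  set.seed(.child_seed(seed, 91))
  E <- cfg$n_electrodes
  k <- length(basis$centers)
  times <- seq(cfg$epoch_window[1], cfg$epoch_window[2],
               by = 1 / cfg$sampling_rate)
  segs <- sort(unique(floor(times[times >= 0] / cfg$segment_len_s)))
  W_stable <- matrix(stats::rnorm(E * k), E, k)
  W_segments <- NULL
  if (cfg$coding_regime != "stable") {
    W_segments <- lapply(segs, function(sg) matrix(stats::rnorm(E * k),
                                                   E, k))
    names(W_segments) <- as.character(segs)
  }
  structure(list(regime = cfg$coding_regime, W_stable = W_stable,
                 W_segments = W_segments),
            class = "weight_schedule")
}

.weights_for_segment <- function(ws, sg) {
  switch(ws$regime,
         stable = ws$W_stable,
         dynamic = ws$W_segments[[as.character(sg)]],
         mixed = (ws$W_stable + ws$W_segments[[as.character(sg)]]) /
           sqrt(2))
}

# Channel input vector for a trial: SO -> basis response to the item
# orientation; VO -> lambda * basis(mean) + (1 - lambda) * average basis
# response over the four item orientations.
.channel_input <- function(stim, lambda, basis) {
  if (stim$condition == "SO") {
    basis_responses(stim$mean_orientation, basis)
  } else {
    items <- unique(stim$item_orientations)
    lambda * basis_responses(stim$mean_orientation, basis) +
      (1 - lambda) * rowMeans(design_matrix(items, basis))
  }
}

#' Simulate epoched signals from the forward model
#'
#' Electrode signals are weighted sums of orientation-channel responses:
#' at each post-onset sample, `signal = W %*% c + noise`, with `W` an
#' electrodes x channels weight matrix (entries i.i.d. standard normal)
#' and `c` the trial's channel-input vector. Before stimulus onset only
#' noise is present. The stable regime holds one `W` for the whole epoch;
#' the dynamic regime redraws `W` independently for every time segment of
#' `segment_len_s`; `mixed` averages a persistent and a redrawn component
#' (each scaled by \eqn{1/\sqrt 2}).
#'
#' @param stimuli List of [stimulus_set()]s (see [generate_stimuli()]).
#' @param cfg A [sim_config()].
#' @param subject_id Label stored in the trial table.
#' @param basis Channel [basis_set()].
#' @param weights Optional [weight_schedule()]. One subject's brain has
#'   one weight schedule: pass the same object when simulating several
#'   conditions of the same subject so that decoders trained on one
#'   condition can generalize to the other. Default: drawn from
#'   `cfg$seed`.
#' @return An [epoch_set()].
#' @export
simulate_epochs <- function(stimuli, cfg, subject_id = "s01",
                            basis = basis_set(), weights = NULL) {
  stopifnot(inherits(cfg, "sim_config"), length(stimuli) >= 1)
  if (is.null(weights)) weights <- weight_schedule(cfg, basis = basis)
  set.seed(cfg$seed)
  n <- length(stimuli)
  E <- cfg$n_electrodes
  k <- length(basis$centers)
  if (nrow(weights$W_stable) != E || ncol(weights$W_stable) != k)
    stop("weight schedule does not match n_electrodes / channel count")
  times <- seq(cfg$epoch_window[1], cfg$epoch_window[2],
               by = 1 / cfg$sampling_rate)
  S <- length(times)
  Ctr <- vapply(stimuli, .channel_input, numeric(k), lambda = cfg$lambda,
                basis = basis)                         # k x n
  post <- times >= 0
  seg <- rep(0L, S)
  seg[post] <- floor(times[post] / cfg$segment_len_s)
  dat <- array(stats::rnorm(n * E * S, sd = cfg$noise_sd), c(n, E, S))
  if (cfg$ar1 != 0) {
    phi <- cfg$ar1
    for (s in 2:S) dat[, , s] <- phi * dat[, , s - 1] +
        sqrt(1 - phi^2) * dat[, , s]
  }
  for (sg in unique(seg[post])) {
    W <- .weights_for_segment(weights, sg)
    sig <- t(W %*% Ctr)                                # n x E
    for (s in which(post & seg == sg)) dat[, , s] <- dat[, , s] + sig
  }
  tt <- data.frame(
    subject_id = subject_id,
    condition = vapply(stimuli, `[[`, character(1), "condition"),
    mean_orientation_bin = match(
      round(vapply(stimuli, `[[`, numeric(1), "mean_orientation"), 6),
      round(stimulus_orientations(), 6)),
    mean_orientation_deg = vapply(stimuli, `[[`, numeric(1),
                                  "mean_orientation"),
    stringsAsFactors = FALSE)
  epoch_set(dat, times, cfg$sampling_rate,
            sprintf("E%02d", seq_len(E)), tt)
}

#' Simulate a multi-subject synthetic experiment
#'
#' Generates SO and VO epoch sets per subject with an independent RNG
#' substream per subject derived from the master seed. Subject-specific
#' `lambda` and `bias_w` values may be supplied (e.g. to tie neural
#' ensemble weight to behavioral bias).
#'
#' @param n_subjects Number of subjects.
#' @param cfg A [sim_config()]; its `seed` is the master seed.
#' @param lambda Optional per-subject vector of ensemble weights.
#' @param bias_w Optional per-subject vector of behavioral biases.
#' @return List with one element per subject: `list(so =, vo =, cfg =)`.
#' @export
simulate_subjects <- function(n_subjects, cfg, lambda = NULL,
                              bias_w = NULL) {
  stopifnot(n_subjects >= 1)
  if (!is.null(lambda)) stopifnot(length(lambda) == n_subjects)
  if (!is.null(bias_w)) stopifnot(length(bias_w) == n_subjects)
  lapply(seq_len(n_subjects), function(i) {
    ci <- cfg
    ci$seed <- .child_seed(cfg$seed, i)
    if (!is.null(lambda)) ci$lambda <- lambda[i]
    if (!is.null(bias_w)) ci$bias_w <- bias_w[i]
    id <- sprintf("s%02d", i)
    so_stim <- generate_stimuli(ci$n_trials_so, "SO", ci$experiment,
                                seed = .child_seed(ci$seed, 101))
    vo_stim <- generate_stimuli(ci$n_trials_vo, "VO", ci$experiment,
                                seed = .child_seed(ci$seed, 202))
    ci_so <- ci; ci_so$seed <- .child_seed(ci$seed, 303)
    ci_vo <- ci; ci_vo$seed <- .child_seed(ci$seed, 404)
    ws <- weight_schedule(ci)      # one brain per subject
    list(subject_id = id,
         so = simulate_epochs(so_stim, ci_so, subject_id = id,
                              weights = ws),
         vo = simulate_epochs(vo_stim, ci_vo, subject_id = id,
                              weights = ws),
         so_stimuli = so_stim, vo_stimuli = vo_stim, cfg = ci,
         weights = ws)
  })
}

#' Probe offsets of the old/new design
#' @param condition `"SO"` or `"VO"`.
#' @return Probe offsets from the mean orientation, degrees (experiment 1
#'   design: VO probes at 0, +/-10..80, -90; SO probes at 0 in half the
#'   trials, else +/-4..32).
#' @export
probe_offsets_oldnew <- function(condition = c("SO", "VO")) {
  condition <- match.arg(condition)
  if (condition == "VO") c(0, c(-1, 1) %o% seq(10, 80, by = 10), -90)
  else c(0, c(-1, 1) %o% seq(4, 32, by = 4))
}

#' Simulate old/new judgments
#'
#' Internal memory for each distinct item orientation is
#' `(1 - w) * item + w * mean` plus circular von Mises noise; the model
#' observer responds "old" when the minimum angular distance from the
#' probe to any memory item is below `criterion_deg`.
#'
#' @param stimuli List of [stimulus_set()]s.
#' @param w Bias toward the mean in `[0, 1]`.
#' @param kappa Response-noise concentration (`Inf` for noiseless).
#' @param criterion_deg Old/new decision criterion, degrees.
#' @param seed Integer seed.
#' @return Data frame of class `behavioral_table_on` with columns
#'   `probe_offset_deg`, `response` ("old"/"new"), `condition`.
#' @export
simulate_oldnew_behavior <- function(stimuli, w = 0.5, kappa = 8,
                                     criterion_deg = 10, seed = 1) {
  stopifnot(length(stimuli) >= 1, w >= 0, w <= 1)
  set.seed(seed)
  rows <- lapply(stimuli, function(stim) {
    offs <- probe_offsets_oldnew(stim$condition)
    if (stim$condition == "SO") {
      # half the trials probe the memorized orientation itself
      probe_off <- if (stats::runif(1) < 0.5) 0 else
        sample(setdiff(offs, 0), 1)
    } else {
      probe_off <- sample(offs, 1)
    }
    probe <- wrap_orientation(stim$mean_orientation + probe_off)
    items <- unique(stim$item_orientations)
    rel <- orientation_diff(items, stim$mean_orientation)
    mem <- vapply(rel, function(r)
      rvm_orientation(1, stim$mean_orientation + (1 - w) * r, kappa),
      numeric(1))
    old <- min(orientation_dist(probe, mem)) < criterion_deg
    data.frame(probe_offset_deg = probe_off,
               response = if (old) "old" else "new",
               condition = stim$condition, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("behavioral_table_on", "data.frame")
  out
}

#' Simulate continuous-estimation responses
#'
#' For VO displays of experiment 2: a random item orientation is cued as
#' the target; the response is `target + w * (mean - target)` plus
#' circular noise, so the expected response error is
#' `-w * target_offset`, a systematic bias toward the ensemble mean.
#'
#' @param stimuli List of VO [stimulus_set()]s (experiment 2).
#' @param w Bias toward the mean in `[0, 1]`.
#' @param kappa Response-noise concentration.
#' @param seed Integer seed.
#' @return Data frame of class `estimation_table` with columns
#'   `target_offset_deg`, `response_error_deg`, `split_label`.
#' @export
simulate_estimation_behavior <- function(stimuli, w = 0.5, kappa = 8,
                                         seed = 1) {
  stopifnot(length(stimuli) >= 1, w >= 0, w <= 1)
  conds <- vapply(stimuli, `[[`, character(1), "condition")
  if (any(conds != "VO"))
    stop("estimation behavior is defined for VO stimuli only ",
         "(no target/mean distinction in SO)")
  set.seed(seed)
  rows <- lapply(stimuli, function(stim) {
    items <- unique(stim$item_orientations)
    target <- sample(items, 1)
    toff <- orientation_diff(target, stim$mean_orientation)
    resp <- rvm_orientation(1, target + w * (-toff), kappa)
    data.frame(target_offset_deg = toff,
               response_error_deg = orientation_diff(resp, target),
               split_label = "unassigned", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("estimation_table", "data.frame")
  out
}

#' Persist an epoch set to a directory
#'
#' Layout: `meta.json` (sampling rate, times, electrode labels),
#' `trials.csv` (the trial table) and `data.bin`, one flat little-endian
#' 64-bit float matrix in trial-major order.
#'
#' @param epochs An [epoch_set()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_epochs <- function(epochs, dir) {
  .validate_epochs(epochs)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(sampling_rate = epochs$sampling_rate, times = epochs$times,
         electrode_labels = epochs$electrode_labels,
         dim = dim(epochs$data)),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(epochs$trial_table, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  con <- file(file.path(dir, "data.bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(epochs$data), con, size = 8, endian = "little")
  invisible(dir)
}

#' Read an epoch set written by [write_epochs()]
#' @param dir Directory.
#' @return An [epoch_set()].
#' @export
read_epochs <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  tt <- utils::read.csv(file.path(dir, "trials.csv"),
                        stringsAsFactors = FALSE)
  con <- file(file.path(dir, "data.bin"), "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = prod(meta$dim), size = 8,
               endian = "little")
  epoch_set(array(v, meta$dim), meta$times, meta$sampling_rate,
            meta$electrode_labels, tt)
}
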