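## Preprocessing for the decoding stages: temporal smoothing,
## downsampling and electrode-subset selection. Acquisition-side steps
## (filtering of continuous recordings, re-referencing, artifact
## rejection) are out of scope; synthetic epochs never need them.

#' Centered moving-average smoothing
#'
#' Boxcar mean over `window_samples` points per trial and electrode
#' (default 51 samples, i.e. a 100 ms sliding window at 500 Hz). Edges
#' use truncated (shrinking) windows so the output length equals the
#' input length; no data are fabricated by padding.
#'
#' @param epochs An [epoch_set()].
#' @param window_samples Odd window length, at most the epoch length.
#' @return Smoothed [epoch_set()] on the same time axis.
#' @export
moving_average <- function(epochs, window_samples = 51) {
  .validate_epochs(epochs)
  S <- dim(epochs$data)[3]
  if (window_samples %% 2 != 1) stop("window must have odd length")
  if (window_samples > S)
    stop("window (", window_samples, ") longer than the epoch (", S, ")")
  h <- (window_samples - 1L) / 2L
  flat <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = S)
  cs <- rbind(0, apply(flat, 2, cumsum))
  hi <- pmin(seq_len(S) + h, S)
  lo <- pmax(seq_len(S) - h, 1L)
  out <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) /
    (hi - lo + 1L)
  epochs$data <- aperm(array(out, c(S, dim(epochs$data)[1],
                                    dim(epochs$data)[2])), c(2, 3, 1))
  epochs
}

#' Downsample epochs to a lower rate
#'
#' Keeps every (native/target)-th sample starting at the first sample of
#' the epoch. No anti-alias filtering beyond the preceding boxcar is
#' applied.
#'
#' @param epochs An [epoch_set()].
#' @param target_rate Target rate in Hz; must divide the native rate.
#' @return Decimated [epoch_set()].
#' @export
downsample <- function(epochs, target_rate = 100) {
  .validate_epochs(epochs)
  fac <- epochs$sampling_rate / target_rate
  if (abs(fac - round(fac)) > 1e-9)
    stop("native rate ", epochs$sampling_rate,
         " Hz is not an integer multiple of ", target_rate, " Hz")
  keep <- seq(1, dim(epochs$data)[3], by = round(fac))
  epochs$data <- epochs$data[, , keep, drop = FALSE]
  epochs$times <- epochs$times[keep]
  epochs$sampling_rate <- target_rate
  epochs
}

#' ROI electrode specification
#'
#' Electrode subsets used to separate frontocentral from
#' occipitoparietal signals. The per-experiment label lists are shipped
#' with the package (`extdata/roi_electrodes.json`); each named ROI has
#' 14 electrodes, the full montage 28.
#'
#' @param name `"all"`, `"frontocentral"` or `"occipitoparietal"`.
#' @param experiment 1 or 2.
#' @return Object of class `roi_spec` with `name`, `experiment`,
#'   `electrode_labels`.
#' @export
roi_spec <- function(name = c("all", "frontocentral", "occipitoparietal"),
                     experiment = 1) {
  name <- match.arg(name)
  if (!experiment %in% c(1, 2)) stop("unknown experiment: ", experiment)
  rois <- jsonlite::read_json(
    system.file("extdata", "roi_electrodes.json", package = "enscode",
                mustWork = TRUE),
    simplifyVector = TRUE)
  structure(list(name = name, experiment = experiment,
                 electrode_labels =
                   rois[[paste0("exp", experiment)]][[name]]),
            class = "roi_spec")
}

#' Restrict epochs to an ROI electrode subset
#'
#' @param epochs An [epoch_set()].
#' @param roi A [roi_spec()] (or a character vector of labels).
#' @return [epoch_set()] restricted to the ROI electrodes, in ROI order.
#' @export
select_electrodes <- function(epochs, roi) {
  .validate_epochs(epochs)
  labels <- if (inherits(roi, "roi_spec")) roi$electrode_labels else roi
  idx <- match(labels, epochs$electrode_labels)
  if (anyNA(idx))
    stop("electrode(s) not present in epochs: ",
         paste(labels[is.na(idx)], collapse = ", "))
  epochs$data <- epochs$data[, idx, , drop = FALSE]
  epochs$electrode_labels <- epochs$electrode_labels[idx]
  epochs
}

#' Equalized random partition with per-orientation averaging
#'
#' Randomly partitions trials into `n_folds` subsets such that every
#' orientation bin contributes the same number of trials to every fold
#' (trials exceeding the equalized count are discarded at random), then
#' averages the trials of each orientation within each fold.
#'
#' @param epochs An [epoch_set()].
#' @param n_folds Number of folds.
#' @param seed Integer seed.
#' @return List: `averages` (array `n_folds` x 8 bins x electrodes x
#'   samples), `fold`/`bin`/`trial` assignment vectors,
#'   `n_per_cell`, `n_discarded`.
#' @export
equalize_and_partition <- function(epochs, n_folds = 3, seed = 1) {
  .validate_epochs(epochs)
  k <- 8L
  bins <- epochs$trial_table$mean_orientation_bin
  set.seed(seed)
  part <- .equalize_partition(bins, n_folds, k)
  Av <- .fold_averages_from_part(epochs$data, part, n_folds, k,
                                 seq_along(epochs$times))
  E <- dim(epochs$data)[2]; S <- dim(epochs$data)[3]
  avg <- array(NA_real_, c(n_folds, k, E, S))
  for (f in seq_len(n_folds))
    avg[f, , , ] <- Av[(f - 1L) * k + seq_len(k), , ]
  list(averages = avg, fold = part$fold, bin = part$bin,
       trial = part$trial, n_per_cell = part$m_per_cell,
       n_discarded = part$discarded)
}
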