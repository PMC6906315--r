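## Trial-wise median-split decoding: the SO-trained decoder is
## generalized separately to the VO trials whose responses fell on the
## "mean" side vs the "target" side of the circular median of the
## re-coded response errors. If only the "mean" trials support stable
## reconstruction of the mean orientation, the cross-condition decoder is
## reading out the ensemble mean rather than the cued item.

#' Subset an epoch set by trial index
#' @param epochs An [epoch_set()].
#' @param idx Integer or logical trial index.
#' @return The restricted [epoch_set()].
#' @export
subset_epochs <- function(epochs, idx) {
  .validate_epochs(epochs)
  epochs$data <- epochs$data[idx, , , drop = FALSE]
  epochs$trial_table <- epochs$trial_table[idx, , drop = FALSE]
  rownames(epochs$trial_table) <- NULL
  epochs
}

#' Median-split cross-condition decoding
#'
#' Splits the VO trials by the labels of [median_split()] (rows of
#' `est_table` align one-to-one with VO trials) and runs the SO-trained
#' cross-condition decoder on each split separately, with the same SO
#' partitions (same seed) for both splits. Within a split the VO test
#' trials are averaged per mean-orientation bin before inversion, which
#' by linearity equals per-trial inversion followed by bin averaging.
#'
#' @param so_epochs,vo_epochs Per-subject [epoch_set()]s.
#' @param est_table An `estimation_table` with `split_label` assigned
#'   (see [median_split()]), one row per VO trial.
#' @param n_folds,n_iterations,seed,times,basis As in
#'   [cross_condition_iem()].
#' @param tg Return full TG matrices (default) or diagonal series.
#' @return Object of class `split_decoding_result`: `tg` (named list with
#'   `mean` and `target` entries), `n_trials` per split.
#' @export
split_decode <- function(so_epochs, vo_epochs, est_table, n_folds = 3,
                         n_iterations = 100, seed = 1, times = NULL,
                         basis = basis_set(), tg = TRUE) {
  .validate_epochs(so_epochs); .validate_epochs(vo_epochs)
  if (nrow(est_table) != dim(vo_epochs$data)[1])
    stop("estimation table (", nrow(est_table), " rows) does not align ",
         "with VO trials (", dim(vo_epochs$data)[1], ")")
  labs <- est_table$split_label
  if (!all(labs %in% c("mean", "target")))
    stop("split labels not assigned; run median_split() first")
  res <- lapply(c(mean = "mean", target = "target"), function(lb) {
    idx <- which(labs == lb)
    if (!length(idx)) stop("empty split: ", lb)
    cross_condition_iem(so_epochs, subset_epochs(vo_epochs, idx),
                        n_folds = n_folds, n_iterations = n_iterations,
                        seed = seed, times = times, basis = basis,
                        tg = tg)
  })
  structure(list(tg = res,
                 n_trials = c(mean = sum(labs == "mean"),
                              target = sum(labs == "target"))),
            class = "split_decoding_result")
}

#' @export
print.split_decoding_result <- function(x, ...) {
  cat("Median-split decoding: ", x$n_trials[["mean"]], " 'mean' vs ",
      x$n_trials[["target"]], " 'target' trials\n", sep = "")
  invisible(x)
}

#' Plot a TG matrix as a heatmap
#'
#' Train time on the y axis, test time on the x axis, optionally masking
#' cells by a significance class.
#'
#' @param tg A [tg_matrix()].
#' @param maps Optional `significance_maps`; significant (non-"neither")
#'   cells are outlined with points.
#' @param main Plot title.
#' @return Invisibly, `tg`.
#' @export
plot_tg_matrix <- function(tg, maps = NULL, main = "TG slope") {
  stopifnot(inherits(tg, "tg_matrix"))
  pal <- grDevices::hcl.colors(64, "RdBu", rev = TRUE)
  lim <- max(abs(tg$slopes))
  graphics::image(tg$times, tg$times, t(tg$slopes), col = pal,
                  zlim = c(-lim, lim), xlab = "test time (s)",
                  ylab = "train time (s)", main = main, useRaster = TRUE)
  if (!is.null(maps)) {
    sig <- which(maps$class != "neither" & !is.na(maps$class),
                 arr.ind = TRUE)
    if (nrow(sig))
      graphics::points(maps$times[sig[, 2]], maps$times[sig[, 1]],
                       pch = ".", col = "black")
  }
  invisible(tg)
}
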