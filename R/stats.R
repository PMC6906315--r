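## Group-level inference: one-sample t statistics, a label-shuffling
## permutation null for the decoding sensitivity, participant-level
## bootstrap standard errors, window-averaged sensitivities and
## brain-behavior correlation.

#' One-sample group t statistic against zero
#'
#' @param values Per-subject values (length >= 2).
#' @return List: `t`, `df`, `mean`, `se`, `degenerate` (TRUE when the
#'   sample variance is zero).
#' @export
group_tstat <- function(values) {
  n <- length(values)
  if (n < 2) stop("need at least 2 subjects")
  s <- stats::sd(values)
  if (s < 1e-14) {
    warning("zero-variance sample: t statistic undefined")
    return(list(t = NA_real_, df = n - 1, mean = mean(values),
                se = 0, degenerate = TRUE))
  }
  se <- s / sqrt(n)
  list(t = mean(values) / se, df = n - 1, mean = mean(values), se = se,
       degenerate = FALSE)
}

#' Label-shuffling permutation test for orientation sensitivity
#'
#' Observed statistic: the group one-sample t of per-subject IEM slopes
#' at the requested time point(s). Null distribution: for each of
#' `n_permutations` permutations, every subject's orientation labels are
#' shuffled jointly across all trials, the IEM is refit and the group t
#' recomputed. The one-tailed p-value uses the add-one rule
#' \eqn{p = (1 + \#\{null \ge observed\}) / (1 + n_{perm})}, which cannot
#' return 0.
#'
#' `n_iterations` defaults to 10 under permutation (a fidelity/runtime
#' knob: each permutation refits the full cross-validated IEM).
#'
#' @param epoch_list List of per-subject [epoch_set()]s. To shuffle
#'   jointly across conditions, pass epochs containing both conditions'
#'   trials.
#' @param time Time point (s) at which to test (a single value).
#' @param n_permutations Number of label shuffles (default 1000).
#' @param n_folds,n_iterations,basis IEM settings.
#' @param seed Integer seed driving shuffles and partitions.
#' @return Object of class `permutation_null`: `observed_t`,
#'   `null_t` (vector), `p`, per-subject observed slopes, settings.
#' @export
permutation_null <- function(epoch_list, time, n_permutations = 1000,
                             n_folds = 3, n_iterations = 10, seed = 1,
                             basis = basis_set()) {
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  stopifnot(length(time) == 1)
  precomp <- .iem_precomp(n_folds, basis)
  k <- length(basis$centers)
  # Single-sample slices: electrodes x trials per subject.
  slices <- lapply(epoch_list, function(ep) {
    .validate_epochs(ep)
    s <- .resolve_times(ep, time)
    list(B = t(ep$data[, , s]), bins = ep$trial_table$mean_orientation_bin)
  })
  n_sub <- length(slices)
  obs_slopes <- vapply(seq_len(n_sub), function(i)
    .iem_slope_single(slices[[i]]$B, slices[[i]]$bins, n_folds,
                      n_iterations, seed = .child_seed(seed, i),
                      basis = basis, precomp = precomp),
    numeric(1))
  observed_t <- group_tstat(obs_slopes)$t
  null_t <- numeric(n_permutations)
  for (p in seq_len(n_permutations)) {
    slopes <- vapply(seq_len(n_sub), function(i) {
      set.seed(.child_seed(seed, 7919 + p * n_sub + i))
      bins_p <- sample(slices[[i]]$bins)
      .iem_slope_single(slices[[i]]$B, bins_p, n_folds, n_iterations,
                        seed = .child_seed(seed, 104729 + p * n_sub + i),
                        basis = basis, precomp = precomp)
    }, numeric(1))
    null_t[p] <- group_tstat(slopes)$t
  }
  pval <- (1 + sum(null_t >= observed_t)) / (1 + n_permutations)
  structure(list(observed_t = observed_t, null_t = null_t, p = pval,
                 observed_slopes = obs_slopes, time = time,
                 n_permutations = n_permutations, n_folds = n_folds,
                 n_iterations = n_iterations, seed = seed),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat("Permutation test (", x$n_permutations, " label shuffles) at t = ",
      x$time, " s\n", sep = "")
  cat("observed t =", format(x$observed_t, digits = 4),
      ", one-tailed p =", format(x$p, digits = 4), "\n")
  invisible(x)
}

#' Bootstrap standard error over participants
#'
#' Draws `n_boot` resamples of the participants with replacement and
#' returns the standard deviation of the resample means.
#'
#' @param values Per-subject values.
#' @param n_boot Number of bootstrap resamples (default 10000).
#' @param seed Integer seed.
#' @return The bootstrap standard error (a single number).
#' @export
bootstrap_se <- function(values, n_boot = 10000, seed = 1) {
  n <- length(values)
  if (n < 1) stop("empty sample")
  set.seed(seed)
  idx <- sample.int(n, n * n_boot, replace = TRUE)
  stats::sd(colMeans(matrix(values[idx], n, n_boot)))
}

#' Window-averaged TG sensitivity
#'
#' Mean TG slope over all cells whose train and test times both fall in
#' the closed window (default 200-1000 ms x 200-1000 ms), one scalar per
#' subject.
#'
#' @param tg A [tg_matrix()] (or a list of them).
#' @param window `c(lo, hi)` in seconds applied to both axes.
#' @return A scalar (or a vector, one per subject).
#' @export
window_average_sensitivity <- function(tg, window = c(0.2, 1.0)) {
  if (is.list(tg) && !inherits(tg, "tg_matrix"))
    return(vapply(tg, window_average_sensitivity, numeric(1),
                  window = window))
  stopifnot(inherits(tg, "tg_matrix"))
  eps <- 1e-9
  sel <- which(tg$times >= window[1] - eps & tg$times <= window[2] + eps)
  if (!length(sel)) stop("window lies outside the epoch time axis")
  mean(tg$slopes[sel, sel])
}

#' Correlate decoding sensitivity with ensemble behavior
#'
#' Ordinary least-squares regression of the behavioral ensemble tendency
#' on the per-subject window-averaged sensitivity (R^2 and regression p),
#' plus the non-parametric Spearman rank correlation as a robustness
#' check.
#'
#' @param sensitivities Per-subject sensitivity scalars.
#' @param tendencies Per-subject behavioral ensemble tendencies.
#' @return Object of class `brain_behavior_result`: `r_squared`, `p`,
#'   `slope`, `spearman_rho`, `spearman_p`, `n`.
#' @export
brain_behavior_correlation <- function(sensitivities, tendencies) {
  stopifnot(length(sensitivities) == length(tendencies))
  n <- length(sensitivities)
  if (n < 3) stop("need at least 3 subjects")
  if (stats::sd(sensitivities) < 1e-14 || stats::sd(tendencies) < 1e-14)
    stop("constant predictor or behavior vector")
  fit <- stats::lm(tendencies ~ sensitivities)
  sm <- summary(fit)
  sp <- suppressWarnings(
    stats::cor.test(sensitivities, tendencies, method = "spearman"))
  structure(list(r_squared = sm$r.squared,
                 p = sm$coefficients[2, 4],
                 slope = stats::coef(fit)[[2]],
                 spearman_rho = unname(sp$estimate),
                 spearman_p = sp$p.value, n = n),
            class = "brain_behavior_result")
}

#' @export
print.brain_behavior_result <- function(x, ...) {
  cat("Brain-behavior correlation (n = ", x$n, ")\n", sep = "")
  cat("R^2 =", format(x$r_squared, digits = 3),
      ", p =", format(x$p, digits = 3),
      "; Spearman rho =", format(x$spearman_rho, digits = 3),
      ", p =", format(x$spearman_p, digits = 3), "\n")
  invisible(x)
}
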