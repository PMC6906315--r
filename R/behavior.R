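## Behavioral analyses. Experiment 1 (old/new judgment): orientation
## similarity, cumulative Weibull psychometric function fit by bounded
## maximum likelihood; its threshold alpha indexes the ensemble tendency.
## Experiment 2 (continuous estimation): response precision, bias toward
## the ensemble mean, and the circular-median split of response errors.

#' Orientation similarity to the mean
#'
#' \eqn{sim(\theta) = 1 - |\theta| / (\pi/2)}, where \eqn{\theta} is the
#' probe orientation relative to the mean orientation, in radians. 1 at
#' the mean, 0 at 90 degrees away.
#'
#' @param theta Probe offset(s) in radians, in \eqn{[-\pi/2, \pi/2]}.
#' @return Similarity value(s) in `[0, 1]`.
#' @export
orientation_similarity <- function(theta) {
  if (any(abs(theta) > pi / 2 + 1e-12))
    stop("theta outside [-pi/2, pi/2]; wrap offsets before calling")
  1 - abs(theta) / (pi / 2)
}

#' Cumulative Weibull psychometric function
#'
#' \eqn{W(sim) = \gamma - (\gamma - \delta) e^{-(sim/\alpha)^\beta}}:
#' predicted proportion of "old" responses at orientation similarity
#' `sim`. `alpha` is the threshold at which the function reaches 63.2%
#' (\eqn{1 - e^{-1}}) of its full amplitude between the lower asymptote
#' `delta` (at sim = 0) and the upper asymptote `gamma`.
#'
#' @param sim Similarity in `[0, 1]`.
#' @param alpha Threshold in (0, 1).
#' @param beta Slope, > 0.
#' @param gamma,delta Upper and lower horizontal asymptotes in (0, 1).
#' @return Predicted proportion(s) of "old" responses.
#' @export
weibull_cdf <- function(sim, alpha, beta, gamma, delta) {
  if (alpha <= 0) stop("alpha must be positive")
  stopifnot(beta > 0)
  gamma - (gamma - delta) * exp(-(sim / alpha)^beta)
}

# Binomial NLL, constant log-choose terms dropped (they do not affect
# the argmin; reported NLL therefore differs from the full pmf by a
# data-dependent constant).
.weibull_nll <- function(par, n, k, sim) {
  w <- weibull_cdf(sim, par[1], par[2], par[3], par[4])
  w <- pmin(pmax(w, 1e-10), 1 - 1e-10)
  -sum(k * log(w) + (n - k) * log(1 - w))
}

#' Fit the cumulative Weibull by maximum likelihood
#'
#' Aggregates the old/new table into per-similarity-level counts and
#' minimizes the binomial negative log-likelihood with a bounded
#' quasi-Newton optimizer, restarted from random initial values: alpha,
#' gamma, delta uniform in (0, 1) and beta uniform in (0, 10). Bounds are
#' alpha, gamma, delta in (0, 1) and beta in (0, 100) (a finite stand-in
#' for an unbounded slope). The restart with the minimal NLL wins.
#'
#' @param table A `behavioral_table_on` data frame with columns
#'   `probe_offset_deg` and `response` ("old"/"new"); VO trials are the
#'   intended input.
#' @param n_restarts Number of random restarts (default 30).
#' @param seed Integer seed for the restart initial values.
#' @return Object of class `weibull_fit`: `alpha`, `beta`, `gamma`,
#'   `delta`, `nll`, `n_restarts_used`, and flags `boundary` (a
#'   parameter ended within tolerance of a bound) and `gamma_lt_delta`
#'   (inverted asymptotes; not prevented, only flagged).
#' @export
fit_weibull_mle <- function(table, n_restarts = 30, seed = 1) {
  if (!nrow(table)) stop("empty behavioral table")
  sim <- orientation_similarity(table$probe_offset_deg * pi / 180)
  lev <- sort(unique(round(sim, 10)))
  if (length(lev) < 2)
    stop("need at least 2 distinct similarity levels")
  grp <- match(round(sim, 10), lev)
  n <- tabulate(grp, length(lev))
  k <- vapply(seq_along(lev), function(i)
    sum(table$response[grp == i] == "old"), integer(1))
  lower <- c(1e-6, 1e-6, 1e-6, 1e-6)
  upper <- c(1 - 1e-9, 100, 1 - 1e-6, 1 - 1e-6)
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- c(stats::runif(1), stats::runif(1, 0, 10), stats::runif(1),
              stats::runif(1))
    init <- pmin(pmax(init, lower + 1e-6), upper - 1e-6)
    fit <- tryCatch(
      stats::optim(init, .weibull_nll, n = n, k = k, sim = lev,
                   method = "L-BFGS-B", lower = lower, upper = upper),
      error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$value) &&
        (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("all optimizer restarts failed")
  par <- best$par
  tol <- 1e-4
  boundary <- any(par - lower < tol) || any(upper - par < tol)
  structure(list(alpha = par[1], beta = par[2], gamma = par[3],
                 delta = par[4], nll = best$value,
                 n_restarts_used = n_restarts,
                 boundary = boundary,
                 gamma_lt_delta = par[3] < par[4],
                 levels = data.frame(sim = lev, n = n, k = k)),
            class = "weibull_fit")
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat("Cumulative Weibull fit (NLL =", format(x$nll, digits = 6), ")\n")
  cat(sprintf("  alpha = %.4f  beta = %.3f  gamma = %.4f  delta = %.4f\n",
              x$alpha, x$beta, x$gamma, x$delta))
  if (x$boundary) cat("  [flag] boundary solution\n")
  if (x$gamma_lt_delta) cat("  [flag] gamma < delta (inverted)\n")
  invisible(x)
}

#' Proportion of "old" responses per probe offset
#'
#' @param table A `behavioral_table_on` data frame.
#' @param offsets Optional vector of offsets to report; absent offsets
#'   are reported as `NA` (missing, not zero).
#' @return Data frame: `probe_offset_deg`, `n`, `k`, `prop_old`.
#' @export
oldnew_tuning_curve <- function(table, offsets = NULL) {
  if (!nrow(table)) stop("empty behavioral table")
  if (is.null(offsets)) offsets <- sort(unique(table$probe_offset_deg))
  out <- do.call(rbind, lapply(offsets, function(o) {
    sel <- table$probe_offset_deg == o
    n <- sum(sel)
    k <- sum(table$response[sel] == "old")
    data.frame(probe_offset_deg = o, n = n, k = k,
               prop_old = if (n > 0) k / n else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

# Re-code response errors so positive = toward the ensemble mean. The
# mean lies at -target_offset relative to the target, so an error e is
# toward the mean when sign(e) == -sign(target_offset).
.toward_mean_errors <- function(table) {
  -sign(table$target_offset_deg) * table$response_error_deg
}

#' Response bias toward the ensemble mean
#'
#' Per-target circular mean of the response errors, sign-flipped so
#' positive = toward the mean orientation; the ensemble tendency is the
#' bias collapsed (averaged) across the four target offsets.
#'
#' @param table An `estimation_table` data frame.
#' @return Object of class `estimation_bias`: data frame `per_target`
#'   (`target_offset_deg`, `n`, `bias_toward_mean_deg`) and scalar
#'   `tendency` (degrees).
#' @export
estimation_bias <- function(table) {
  targets <- sort(unique(table$target_offset_deg))
  if (length(targets) < 1) stop("empty estimation table")
  per <- do.call(rbind, lapply(targets, function(tg) {
    sel <- table$target_offset_deg == tg
    if (!sum(sel)) stop("missing target level ", tg)
    raw <- circ_mean_orientation(table$response_error_deg[sel])
    data.frame(target_offset_deg = tg, n = sum(sel),
               bias_toward_mean_deg = -sign(tg) * raw)
  }))
  rownames(per) <- NULL
  structure(list(per_target = per,
                 tendency = mean(per$bias_toward_mean_deg)),
            class = "estimation_bias")
}

#' @export
print.estimation_bias <- function(x, ...) {
  print(x$per_target)
  cat("ensemble tendency (mean toward-mean bias):",
      format(x$tendency, digits = 4), "deg\n")
  invisible(x)
}

#' Precision of continuous-estimation responses
#'
#' Precision is the reciprocal of the circular standard deviation of the
#' response errors, in 1/degrees. (The original figure axis never defines
#' "precision"; reciprocal circular SD is this package's stand-in.)
#'
#' @param table An `estimation_table` data frame (>= 2 trials).
#' @return List: `precision` (deg^-1), `circ_sd_deg`, `infinite` flag
#'   (zero dispersion).
#' @export
estimation_precision <- function(table) {
  if (nrow(table) < 2) stop("need at least 2 trials")
  s <- circ_sd_orientation(table$response_error_deg)
  if (s < 1e-12) {
    warning("zero dispersion: infinite precision")
    return(list(precision = Inf, circ_sd_deg = 0, infinite = TRUE))
  }
  list(precision = 1 / s, circ_sd_deg = s, infinite = FALSE)
}

#' Circular-median split of estimation trials
#'
#' Response errors are re-coded so positive = toward the ensemble mean;
#' the circular median of the re-coded errors (which lies between the
#' mean and the target orientations) splits the trials: strictly above
#' the median -> "mean" response trials, strictly below -> "target"
#' response trials, ties at the median -> "mean" (deterministic,
#' order-independent tie rule).
#'
#' @param table An `estimation_table` with >= 4 trials.
#' @return The table with `split_label` filled in ("mean"/"target") and
#'   attribute `median_toward_mean_deg`.
#' @export
median_split <- function(table) {
  if (nrow(table) < 4) stop("need at least 4 trials to split")
  r <- .toward_mean_errors(table)
  if (max(orientation_dist(r, r[1])) < 1e-9)
    stop("degenerate split: all re-coded errors identical")
  med <- circ_median_orientation(r)
  rel <- orientation_diff(r, med)
  table$split_label <- ifelse(rel >= 0, "mean", "target")
  attr(table, "median_toward_mean_deg") <- med
  table
}
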