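## Inverted encoding model (IEM) core.
##
## Model: B = W C, with B (m electrodes x n observations) the measured
## signal at one time point, W (m x k) an electrode-by-channel weight
## matrix and C (k x n) the channel tuning function (CTF) matrix built
## from a cosine-power basis. Training estimates W by least squares;
## testing inverts the estimate to reconstruct channel responses.

#' The eight stimulus orientations used throughout
#'
#' Mean orientations are drawn from a fixed grid of eight orientations
#' spaced 22.5 degrees apart.
#'
#' @return Numeric vector of 8 orientations in degrees.
#' @export
stimulus_orientations <- function() {
  seq(-78.75, 78.75, by = 22.5)
}

# Aligned channel-offset axis (relative to the stimulus orientation) and
# the folded axis used by the slope statistic: channels at +22.5, +45 and
# +67.5 have their signs reversed, giving
# (-90, -67.5, -45, -22.5, 0, -22.5, -45, -67.5).
.aligned_offsets <- function() seq(-90, 67.5, by = 22.5)
.folded_axis <- function() -abs(.aligned_offsets())

#' Construct a channel basis set
#'
#' Eight orientation channels centered on the stimulus orientations, each
#' responding as \eqn{R = \cos^7(\Delta)} to an orientation offset
#' \eqn{\Delta} (in radians), so the response is 1 at the channel center
#' and 0 at 90 degrees away.
#'
#' @param centers Channel center orientations in degrees; default the
#'   eight stimulus orientations.
#' @param exponent Cosine power; default 7.
#' @return Object of class `basis_set`.
#' @export
basis_set <- function(centers = stimulus_orientations(), exponent = 7) {
  stopifnot(length(centers) >= 2, exponent > 0)
  centers <- wrap_orientation(centers)
  if (anyDuplicated(centers))
    stop("channel centers must be distinct orientations")
  structure(list(centers = centers, exponent = exponent),
            class = "basis_set")
}

#' @export
print.basis_set <- function(x, ...) {
  cat("Channel basis: ", length(x$centers), " channels, cos^",
      x$exponent, " tuning\n", sep = "")
  cat("Centers (deg):", paste(format(x$centers), collapse = ", "), "\n")
  invisible(x)
}

#' Channel responses to an orientation
#'
#' Response of each basis channel to orientation(s) `theta`:
#' \eqn{\cos^p(\Delta \pi / 180)} with \eqn{\Delta} the wrapped offset from
#' the channel center in \eqn{[-90, 90]} degrees.
#'
#' @param theta Orientation(s) in degrees.
#' @param basis A [basis_set()].
#' @return A k-vector for scalar `theta`, else a k x length(theta) matrix.
#' @examples
#' basis_responses(0, basis_set(centers = seq(-90, 67.5, by = 22.5)))
#' @export
basis_responses <- function(theta, basis = basis_set()) {
  delta <- outer(basis$centers, wrap_orientation(theta), orientation_diff)
  r <- cos(delta * pi / 180)^basis$exponent
  if (length(theta) == 1L) drop(r) else r
}

#' Design (CTF) matrix for a set of observed orientations
#'
#' @param theta Orientations in degrees, one per observation.
#' @param basis A [basis_set()].
#' @return k channels x n observations matrix of basis responses.
#' @export
design_matrix <- function(theta, basis = basis_set()) {
  C <- basis_responses(theta, basis)
  if (is.null(dim(C))) C <- matrix(C, ncol = 1)
  C
}

#' Estimate the electrode-by-channel weight matrix
#'
#' Least-squares solution \eqn{\hat W = B_1 C_1^T (C_1 C_1^T)^{-1}} of the
#' forward model \eqn{B_1 = W C_1}.
#'
#' @param B1 m electrodes x n observations training signal.
#' @param C1 k channels x n observations design matrix.
#' @return m x k weight matrix.
#' @export
estimate_weights <- function(B1, C1) {
  stopifnot(is.matrix(B1), is.matrix(C1), ncol(B1) == ncol(C1))
  G <- tcrossprod(C1)
  qrG <- qr(G)
  if (qrG$rank < nrow(C1)) {
    covered <- apply(C1, 1, function(r) any(abs(r - 1) < 1e-8))
    stop("design matrix is rank deficient (C1 C1' singular); ",
         "channels without a matching orientation: ",
         paste(which(!covered), collapse = ", "))
  }
  t(solve(qrG, C1 %*% t(B1)))
}

#' Invert estimated weights to reconstruct channel responses
#'
#' \eqn{\hat C_2 = (\hat W^T \hat W)^{-1} \hat W^T B_2}.
#'
#' @param W m electrodes x k channels weight matrix.
#' @param B2 m x n test signal.
#' @return k x n reconstructed channel-response matrix.
#' @export
invert_to_ctf <- function(W, B2) {
  stopifnot(is.matrix(W), is.matrix(B2), nrow(W) == nrow(B2))
  if (nrow(W) < ncol(W))
    stop("fewer electrodes than channels: W'W is singular")
  G <- crossprod(W)
  if (qr(G)$rank < ncol(W))
    stop("rank-deficient weight matrix: W'W is singular")
  solve(G, crossprod(W, B2))
}

#' Baseline-correct channel responses
#'
#' Subtracts, per observation (column), the mean response over all
#' channels, so corrected responses sum to zero. Idempotent.
#'
#' @param ctf k channels x n observations matrix (or a k-vector).
#' @return Same shape, baseline corrected.
#' @export
baseline_correct <- function(ctf) {
  if (is.null(dim(ctf))) return(ctf - mean(ctf))
  sweep(ctf, 2, colMeans(ctf))
}

# Row index of the channel sitting at aligned-offset position p for
# orientation bin o: centers[idx[p, o]] == wrap(center_o + offset_p).
.alignment_index <- function(basis = basis_set()) {
  off <- .aligned_offsets()
  k <- length(basis$centers)
  idx <- matrix(NA_integer_, k, k)
  for (o in seq_len(k)) {
    want <- wrap_orientation(basis$centers[o] + off)
    idx[, o] <- match(round(want, 6), round(basis$centers, 6))
  }
  if (anyNA(idx))
    stop("channel centers do not form a closed 22.5-degree grid")
  idx
}

#' Align per-orientation CTFs to a common center and average
#'
#' Each orientation bin's reconstructed profile is circularly shifted so
#' that the channel matching its own orientation sits at the 0-degree
#' offset position, then the eight aligned profiles are averaged.
#'
#' @param ctf k channels x k orientation-bins matrix; column `o` is the
#'   (baseline-corrected) profile for orientation bin `o`.
#' @param basis A [basis_set()] giving the bin/channel centers.
#' @return Object of class `ctf`: the aligned averaged profile on the
#'   offset axis (-90, -67.5, ..., 67.5) degrees.
#' @export
align_and_average <- function(ctf, basis = basis_set()) {
  k <- length(basis$centers)
  stopifnot(is.matrix(ctf), nrow(ctf) == k)
  if (ncol(ctf) != k)
    stop("need one profile per orientation bin (missing orientation bin)")
  if (anyNA(ctf)) stop("missing orientation bin (NA profile)")
  idx <- .alignment_index(basis)
  aligned <- vapply(seq_len(k), function(o) ctf[idx[, o], o],
                    numeric(k))
  structure(list(offsets = .aligned_offsets(),
                 responses = rowMeans(aligned),
                 n_profiles = k),
            class = "ctf")
}

#' @export
print.ctf <- function(x, ...) {
  cat("Aligned channel tuning function (average of", x$n_profiles,
      "profiles)\n")
  print(stats::setNames(round(x$responses, 4), format(x$offsets)))
  cat("slope:", format(ctf_slope(x)), "per degree\n")
  invisible(x)
}

#' CTF slope (orientation sensitivity)
#'
#' Signs of the offsets +22.5, +45 and +67.5 are reversed so the folded
#' axis reads (-90, -67.5, -45, -22.5, 0, -22.5, -45, -67.5); the slope is
#' the OLS regression slope (with intercept) of the eight aligned channel
#' responses on that axis. Zero for flat profiles, positive for
#' center-peaked tuning.
#'
#' @param ctf A [align_and_average()] result or an 8-vector of aligned
#'   responses on the offset axis (-90, ..., 67.5).
#' @return Slope in response units per degree.
#' @export
ctf_slope <- function(ctf) {
  r <- if (inherits(ctf, "ctf")) ctf$responses else ctf
  stopifnot(length(r) == length(.aligned_offsets()))
  sum(.slope_weights() * r)
}

# OLS slope as a linear functional: weights (x - xbar) / sum((x - xbar)^2)
# on the folded axis. They sum to zero, so intercept and baseline offsets
# drop out.
.slope_weights <- function() {
  x <- .folded_axis()
  xc <- x - mean(x)
  xc / sum(xc^2)
}

# L[channel, orientation-bin]: slope of the aligned-averaged
# baseline-corrected CTF as a linear functional of the raw k x k
# reconstruction, slope = sum(L * C2hat). Exists because baseline
# correction, circular alignment, averaging and the OLS slope are all
# linear maps.
.slope_functional <- function(basis = basis_set()) {
  idx <- .alignment_index(basis)
  w <- .slope_weights()
  k <- length(basis$centers)
  L <- matrix(0, k, k)
  for (o in seq_len(k)) L[idx[, o], o] <- L[idx[, o], o] + w / k
  L
}

## ---- cross-validated drivers -------------------------------------------

# Random equalized partition of trials into folds: per orientation bin,
# keep n_folds * m trials (m = floor(min bin count / n_folds)) so every
# bin contributes the same count to every fold; the rest are discarded.
.equalize_partition <- function(bins, n_folds, k) {
  counts <- tabulate(bins, nbins = k)
  if (any(counts < n_folds))
    stop("orientation bin(s) with fewer trials than folds: ",
         paste(which(counts < n_folds), collapse = ", "))
  m <- min(counts) %/% n_folds
  trial <- integer(0); fold <- integer(0); bin <- integer(0)
  for (b in seq_len(k)) {
    idx <- sample(which(bins == b))
    keep <- idx[seq_len(m * n_folds)]
    trial <- c(trial, keep)
    fold <- c(fold, rep(seq_len(n_folds), each = m))
    bin <- c(bin, rep(b, m * n_folds))
  }
  list(trial = trial, fold = fold, bin = bin, m_per_cell = m,
       discarded = sum(counts) - k * m * n_folds)
}

# Resolve requested time points to sample indices.
.resolve_times <- function(epochs, times) {
  if (is.null(times)) return(seq_along(epochs$times))
  idx <- vapply(times, function(t) {
    j <- which(abs(epochs$times - t) < 1e-9)
    if (!length(j)) stop("requested time ", t, " s not on the epoch grid")
    j[1]
  }, integer(1))
  idx
}

#' Cross-validated IEM orientation sensitivity over time
#'
#' For each random equalized partition (iteration) and each fold, weights
#' are estimated per time point from the per-orientation averaged training
#' signals, inverted on the held-out fold's averaged signals, and the
#' reconstructed profiles are baseline-corrected, circularly aligned,
#' averaged over the eight orientations and summarized by the CTF slope.
#' Slopes are averaged over folds and iterations.
#'
#' @param epochs An [epoch_set()].
#' @param n_folds Number of cross-validation folds (default 3).
#' @param n_iterations Number of random re-partitions (default 100).
#' @param seed Integer seed controlling all partitions.
#' @param times Optional numeric vector of time points (s) to decode;
#'   default all.
#' @param basis Channel [basis_set()].
#' @return Object of class `sensitivity_series`: `times`, `slope`, and
#'   run metadata.
#' @export
run_iem <- function(epochs, n_folds = 3, n_iterations = 100, seed = 1,
                    times = NULL, basis = basis_set()) {
  .validate_epochs(epochs)
  k <- length(basis$centers)
  sample_idx <- .resolve_times(epochs, times)
  S <- length(sample_idx)
  bins <- epochs$trial_table$mean_orientation_bin
  L <- .slope_functional(basis)
  C8 <- design_matrix(basis$centers, basis)
  C1 <- do.call(cbind, rep(list(C8), n_folds - 1))
  P1 <- t(C1) %*% solve(tcrossprod(C1))
  acc <- numeric(S)
  discarded <- NA_integer_
  for (it in seq_len(n_iterations)) {
    set.seed(.child_seed(seed, it))
    part <- .equalize_partition(bins, n_folds, k)
    discarded <- part$discarded
    Av <- .fold_averages_from_part(epochs$data, part, n_folds, k,
                                   sample_idx)
    for (f in seq_len(n_folds)) {
      tr <- which(rep(seq_len(n_folds), each = k) != f)
      te <- which(rep(seq_len(n_folds), each = k) == f)
      for (s in seq_len(S)) {
        W <- t(Av[tr, , s]) %*% P1
        C2 <- solve(crossprod(W), t(W)) %*% t(Av[te, , s])
        acc[s] <- acc[s] + sum(L * C2)
      }
    }
  }
  structure(list(times = epochs$times[sample_idx],
                 slope = acc / (n_folds * n_iterations),
                 n_folds = n_folds, n_iterations = n_iterations,
                 seed = seed, n_discarded = discarded,
                 sampling_rate = epochs$sampling_rate),
            class = "sensitivity_series")
}

# Fold averaging given a fixed partition (so drivers sharing a seed share
# partitions exactly).
.fold_averages_from_part <- function(data, part, n_folds, k, sample_idx) {
  dat <- data[part$trial, , sample_idx, drop = FALSE]
  gid <- (part$fold - 1L) * k + part$bin
  E <- dim(dat)[2]; S <- dim(dat)[3]
  flat <- matrix(dat, nrow = dim(dat)[1])
  avg <- rowsum(flat, gid, reorder = TRUE) / part$m_per_cell
  array(avg, c(n_folds * k, E, S))
}

# Inversion without the per-call rank ceremony of invert_to_ctf; errors
# bubble up from solve() on exact singularity.
.invert_fast <- function(W, B2) {
  solve(crossprod(W), crossprod(W, B2))
}

#' @export
print.sensitivity_series <- function(x, ...) {
  cat("IEM sensitivity series: ", length(x$times), " time points (",
      format(min(x$times)), "..", format(max(x$times)), " s), ",
      x$n_folds, "-fold x ", x$n_iterations, " iterations\n", sep = "")
  cat("slope range:", format(range(x$slope), digits = 4), "\n")
  invisible(x)
}

#' @export
as.data.frame.sensitivity_series <- function(x, ...) {
  data.frame(time = x$times, slope = x$slope)
}

#' Cross-condition generalization: train on SO, test on VO
#'
#' Weights are trained on random folds of the same-orientation (SO)
#' condition exactly as in [run_iem()]; at test, they are applied to all
#' varied-orientation (VO) trials, labelled by the *mean* orientation of
#' their display and averaged per mean-orientation bin before inversion
#' (per-trial inversion gives identical bin averages by linearity).
#'
#' @param so_epochs,vo_epochs [epoch_set()]s sharing electrodes, sampling
#'   rate and time axis.
#' @param n_folds,n_iterations,seed,times,basis As in [run_iem()].
#' @param tg If `TRUE`, return the full train-time x test-time
#'   [tg_matrix()]-style matrix instead of the diagonal series.
#' @return A `sensitivity_series` (or a `tg_matrix` when `tg = TRUE`).
#' @export
cross_condition_iem <- function(so_epochs, vo_epochs, n_folds = 3,
                                n_iterations = 100, seed = 1,
                                times = NULL, basis = basis_set(),
                                tg = FALSE) {
  .validate_epochs(so_epochs); .validate_epochs(vo_epochs)
  if (!identical(so_epochs$electrode_labels, vo_epochs$electrode_labels))
    stop("SO and VO epochs have different electrode sets")
  if (!isTRUE(all.equal(so_epochs$times, vo_epochs$times)) ||
      so_epochs$sampling_rate != vo_epochs$sampling_rate)
    stop("SO and VO epochs are on different time grids")
  k <- length(basis$centers)
  sample_idx <- .resolve_times(so_epochs, times)
  vo_bins <- vo_epochs$trial_table$mean_orientation_bin
  if (!all(seq_len(k) %in% vo_bins))
    stop("missing mean-orientation bin in VO trials: ",
         paste(setdiff(seq_len(k), unique(vo_bins)), collapse = ", "))
  # Per-bin averaged VO test signal, fixed across folds and iterations.
  Bvo <- .bin_averages(vo_epochs$data, vo_bins, k, sample_idx)
  .iem_engine_train_so(so_epochs, Bvo, n_folds, n_iterations, seed,
                       sample_idx, basis, tg)
}

# Average trials per orientation bin -> array (k, E, S).
.bin_averages <- function(data, bins, k, sample_idx) {
  dat <- data[, , sample_idx, drop = FALSE]
  flat <- matrix(dat, nrow = dim(dat)[1])
  avg <- rowsum(flat, bins, reorder = TRUE) / as.vector(table(bins))
  array(avg, c(k, dim(dat)[2], length(sample_idx)))
}

# Shared SO-trained engine: test signal `Btest` is a fixed (k, E, S)
# array (cross-condition) applied after every training fold.
.iem_engine_train_so <- function(so_epochs, Btest, n_folds, n_iterations,
                                 seed, sample_idx, basis, tg) {
  k <- length(basis$centers)
  S <- length(sample_idx)
  bins <- so_epochs$trial_table$mean_orientation_bin
  L <- .slope_functional(basis)
  C8 <- design_matrix(basis$centers, basis)
  C1 <- do.call(cbind, rep(list(C8), n_folds - 1))
  P1 <- t(C1) %*% solve(tcrossprod(C1))
  acc <- if (tg) matrix(0, S, S) else numeric(S)
  B2_stack <- matrix(aperm(Btest, c(2, 1, 3)), nrow = dim(Btest)[2])
  for (it in seq_len(n_iterations)) {
    set.seed(.child_seed(seed, it))
    part <- .equalize_partition(bins, n_folds, k)
    Av <- .fold_averages_from_part(so_epochs$data, part, n_folds, k,
                                   sample_idx)
    for (f in seq_len(n_folds)) {
      tr <- which(rep(seq_len(n_folds), each = k) != f)
      if (tg) {
        A_stack <- matrix(0, k * S, dim(Btest)[2])
        for (s in seq_len(S)) {
          W <- t(Av[tr, , s]) %*% P1
          A_stack[(s - 1L) * k + seq_len(k), ] <-
            solve(crossprod(W), t(W))
        }
        P <- A_stack %*% B2_stack
        acc <- acc + .contract_slopes(P, L, S)
      } else {
        for (s in seq_len(S)) {
          W <- t(Av[tr, , s]) %*% P1
          C2 <- .invert_fast(W, t(Btest[, , s]))
          acc[s] <- acc[s] + sum(L * C2)
        }
      }
    }
  }
  val <- acc / (n_folds * n_iterations)
  times <- so_epochs$times[sample_idx]
  if (tg) {
    structure(list(times = times, slopes = val, n_folds = n_folds,
                   n_iterations = n_iterations, seed = seed,
                   sampling_rate = so_epochs$sampling_rate,
                   train = "SO", test = "VO"),
              class = "tg_matrix")
  } else {
    structure(list(times = times, slope = val, n_folds = n_folds,
                   n_iterations = n_iterations, seed = seed,
                   n_discarded = NA_integer_,
                   sampling_rate = so_epochs$sampling_rate),
              class = "sensitivity_series")
  }
}

# Contract the stacked reconstruction P ((k*S_train) x (k*S_test); block
# (t1,t2) = A(t1) %*% B2(t2)) against the slope functional L.
.contract_slopes <- function(P, L, S) {
  k <- nrow(L)
  out <- matrix(0, S, S)
  for (ch in seq_len(k)) {
    rs <- seq(ch, by = k, length.out = S)
    for (o in seq_len(k)) {
      if (L[ch, o] == 0) next
      out <- out + L[ch, o] * P[rs, seq(o, by = k, length.out = S)]
    }
  }
  out
}

## Fast single-time-point IEM slope used by the permutation machinery.
## B: electrodes x trials at one sample; bins: orientation bin per trial.
.iem_slope_single <- function(B, bins, n_folds = 3, n_iterations = 10,
                              seed = 1, basis = basis_set(),
                              precomp = NULL) {
  k <- length(basis$centers)
  if (is.null(precomp)) precomp <- .iem_precomp(n_folds, basis)
  acc <- 0
  for (it in seq_len(n_iterations)) {
    set.seed(.child_seed(seed, it))
    part <- .equalize_partition(bins, n_folds, k)
    gid <- (part$fold - 1L) * k + part$bin
    G <- rowsum(t(B[, part$trial, drop = FALSE]), gid,
                reorder = TRUE) / part$m_per_cell   # (n_folds*k) x E
    for (f in seq_len(n_folds)) {
      tr <- which(rep(seq_len(n_folds), each = k) != f)
      te <- which(rep(seq_len(n_folds), each = k) == f)
      W <- t(G[tr, , drop = FALSE]) %*% precomp$P1
      C2 <- solve(crossprod(W), crossprod(W, t(G[te, , drop = FALSE])))
      acc <- acc + sum(precomp$L * C2)
    }
  }
  acc / (n_folds * n_iterations)
}

.iem_precomp <- function(n_folds, basis = basis_set()) {
  C8 <- design_matrix(basis$centers, basis)
  C1 <- do.call(cbind, rep(list(C8), n_folds - 1))
  list(P1 = t(C1) %*% solve(tcrossprod(C1)),
       L = .slope_functional(basis))
}
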