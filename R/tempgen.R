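## Temporal generalization (TG) of the IEM and the stable/dynamic coding
## index. A TG matrix trains the decoder at time t1 and tests it at time
## t2 for all pairs; stable coding shows as significant off-diagonal
## generalization not below the diagonals, dynamic coding as off-diagonal
## cells significantly below both corresponding diagonal cells.

#' Temporal-generalization matrix of CTF slopes
#'
#' For every pair (t1, t2), weights are estimated at train time t1 on the
#' averaged training folds and inverted at test time t2 on the held-out
#' fold; the CTF slope of the reconstruction fills cell (t1, t2). Folds
#' and iterations are shared across the whole matrix, so with the same
#' `seed` the diagonal reproduces [run_iem()].
#'
#' @inheritParams run_iem
#' @return Object of class `tg_matrix`: `times`, `slopes` (train-time x
#'   test-time matrix) and run metadata.
#' @export
tg_matrix <- function(epochs, n_folds = 3, n_iterations = 100, seed = 1,
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
  E <- dim(epochs$data)[2]
  acc <- matrix(0, S, S)
  for (it in seq_len(n_iterations)) {
    set.seed(.child_seed(seed, it))
    part <- .equalize_partition(bins, n_folds, k)
    Av <- .fold_averages_from_part(epochs$data, part, n_folds, k,
                                   sample_idx)
    for (f in seq_len(n_folds)) {
      tr <- which(rep(seq_len(n_folds), each = k) != f)
      te <- which(rep(seq_len(n_folds), each = k) == f)
      A_stack <- matrix(0, k * S, E)
      for (s in seq_len(S)) {
        W <- t(Av[tr, , s]) %*% P1
        A_stack[(s - 1L) * k + seq_len(k), ] <- solve(crossprod(W), t(W))
      }
      B2_stack <- matrix(aperm(array(Av[te, , , drop = FALSE],
                                     c(k, E, S)), c(2, 1, 3)), nrow = E)
      acc <- acc + .contract_slopes(A_stack %*% B2_stack, L, S)
    }
  }
  structure(list(times = epochs$times[sample_idx],
                 slopes = acc / (n_folds * n_iterations),
                 n_folds = n_folds, n_iterations = n_iterations,
                 seed = seed, sampling_rate = epochs$sampling_rate,
                 train = "within", test = "within"),
            class = "tg_matrix")
}

#' @export
print.tg_matrix <- function(x, ...) {
  cat("TG matrix (", x$train, " -> ", x$test, "): ", length(x$times),
      " x ", length(x$times), " time points, ", x$n_folds, "-fold x ",
      x$n_iterations, " iterations\n", sep = "")
  cat("slope range:", format(range(x$slopes), digits = 4), "\n")
  invisible(x)
}

#' Diagonal of a TG matrix as a sensitivity series
#' @param tg A [tg_matrix()].
#' @return A `sensitivity_series`.
#' @export
tg_diagonal <- function(tg) {
  stopifnot(inherits(tg, "tg_matrix"))
  structure(list(times = tg$times, slope = diag(tg$slopes),
                 n_folds = tg$n_folds, n_iterations = tg$n_iterations,
                 seed = tg$seed, n_discarded = NA_integer_,
                 sampling_rate = tg$sampling_rate),
            class = "sensitivity_series")
}

#' Classify TG cells as stable, dynamic or neither
#'
#' For every off-diagonal cell (t1, t2) three one-sided hypotheses are
#' tested across subjects: H1, TG(t1,t2) < TG(t1,t1); H2, TG(t1,t2) <
#' TG(t2,t2); H3, TG(t1,t2) > 0. A cell is *dynamic* when H1 and H2 both
#' hold, *stable* when neither H1 nor H2 holds but H3 does; the classes
#' are mutually exclusive by construction.
#'
#' @param tg_list List of per-subject [tg_matrix()]s (or slope matrices)
#'   on a common time grid; at least 2 subjects.
#' @param alpha Per-cell significance level (one-sided, uncorrected).
#' @param method `"parametric"` (one-sided paired/one-sample t-tests) or
#'   `"permutation"` (sign-flip randomization of the per-subject
#'   differences, group mean statistic, add-one p-value).
#' @param n_flips Number of sign flips for `method = "permutation"`.
#' @param seed Seed for the sign flips.
#' @return Object of class `significance_maps`: logical `H1`, `H2`, `H3`
#'   matrices (NA on the diagonal), a `class` matrix with values
#'   `"stable"`, `"dynamic"`, `"neither"` (NA on the diagonal), and
#'   metadata.
#' @export
classify_cells <- function(tg_list, alpha = 0.05,
                           method = c("parametric", "permutation"),
                           n_flips = 2000, seed = 1) {
  method <- match.arg(method)
  mats <- lapply(tg_list, function(x)
    if (inherits(x, "tg_matrix")) x$slopes else x)
  n <- length(mats)
  if (n < 2) stop("need at least 2 subjects")
  S <- nrow(mats[[1]])
  times <- if (inherits(tg_list[[1]], "tg_matrix")) tg_list[[1]]$times
           else seq_len(S)
  X <- array(unlist(mats), c(S, S, n))
  # Per-subject differences against the two corresponding diagonal cells.
  D1 <- X; D2 <- X
  for (s in seq_len(n)) {
    d <- diag(X[, , s])
    D1[, , s] <- X[, , s] - d          # column-recycled: subtracts d[t1]
    D2[, , s] <- t(t(X[, , s]) - d)    # subtracts d[t2]
  }
  flat <- function(A) t(matrix(A, S * S, n))     # subjects x cells
  degenerate <- 0L
  if (method == "parametric") {
    tst <- function(M) {               # one-sample t per cell (column)
      mu <- colMeans(M)
      sd <- sqrt(colMeans(sweep(M, 2, mu)^2) * n / (n - 1))
      zero <- sd < 1e-14
      degenerate <<- degenerate + sum(zero & abs(mu) > 1e-14)
      t <- ifelse(sd > 0, mu / (sd / sqrt(n)), 0)
      t
    }
    df <- n - 1
    H1 <- tst(flat(D1)) < stats::qt(alpha, df)
    H2 <- tst(flat(D2)) < stats::qt(alpha, df)
    H3 <- tst(flat(X)) > stats::qt(1 - alpha, df)
  } else {
    set.seed(seed)
    flips <- matrix(sample(c(-1, 1), n_flips * n, replace = TRUE),
                    n_flips, n)
    pperm <- function(M, side) {
      obs <- colMeans(M)
      exceed <- integer(length(obs))
      for (start in seq(1, n_flips, by = 500)) {
        idx <- start:min(start + 499, n_flips)
        nullm <- flips[idx, , drop = FALSE] %*% M / n
        exceed <- exceed + if (side == "less")
          colSums(nullm <= rep(obs, each = length(idx))) else
          colSums(nullm >= rep(obs, each = length(idx)))
      }
      (1 + exceed) / (1 + n_flips)
    }
    H1 <- pperm(flat(D1), "less") < alpha
    H2 <- pperm(flat(D2), "less") < alpha
    H3 <- pperm(flat(X), "greater") < alpha
  }
  shape <- function(h) { m <- matrix(h, S, S); diag(m) <- NA; m }
  H1 <- shape(H1); H2 <- shape(H2); H3 <- shape(H3)
  cls <- matrix("neither", S, S)
  cls[H1 & H2] <- "dynamic"
  cls[!H1 & !H2 & H3] <- "stable"
  diag(cls) <- NA
  structure(list(H1 = H1, H2 = H2, H3 = H3, class = cls,
                 alpha = alpha, method = method, times = times,
                 n_subjects = n, n_degenerate = degenerate),
            class = "significance_maps")
}

#' @export
print.significance_maps <- function(x, ...) {
  cat("Significance maps (", x$method, ", alpha = ", x$alpha, ", n = ",
      x$n_subjects, " subjects)\n", sep = "")
  print(table(x$class, useNA = "no"))
  invisible(x)
}

#' Construct significance maps directly
#'
#' Builds a `significance_maps` object from explicit H1/H2/H3 matrices
#' (used for analytic edge cases and tests).
#'
#' @param H1,H2,H3 Logical square matrices; diagonals are set to NA.
#' @param times Time axis in seconds.
#' @param alpha,method Metadata.
#' @return A `significance_maps` object.
#' @export
significance_maps <- function(H1, H2, H3, times,
                              alpha = 0.05, method = "constructed") {
  S <- length(times)
  stopifnot(all(dim(H1) == c(S, S)), all(dim(H2) == c(S, S)),
            all(dim(H3) == c(S, S)))
  shape <- function(h) { h <- as.matrix(h); diag(h) <- NA; h }
  H1 <- shape(H1); H2 <- shape(H2); H3 <- shape(H3)
  cls <- matrix("neither", S, S)
  cls[H1 & H2] <- "dynamic"
  cls[!H1 & !H2 & H3] <- "stable"
  diag(cls) <- NA
  structure(list(H1 = H1, H2 = H2, H3 = H3, class = cls, alpha = alpha,
                 method = method, times = times,
                 n_subjects = NA_integer_, n_degenerate = 0L),
            class = "significance_maps")
}

#' Stable and dynamic coding indices over time
#'
#' At each time point t, the index is the proportion of significantly
#' stable (resp. dynamic) cells among the eligible cells of a square
#' window of `window_ms` centered on (t, t), excluding cells within
#' `guard_ms` of the diagonal (inclusive) to control the temporal
#' smearing of the moving-average filter. The window is truncated at the
#' epoch boundaries and the denominator adapts. An index of 1 means the
#' TG is completely stable (or dynamic) around t; 0 means not at all.
#'
#' @param maps A `significance_maps` object on a uniform time grid.
#' @param window_ms Square window size in ms (default 310).
#' @param guard_ms Diagonal exclusion half-width in ms (default 50).
#' @return Object of class `sd_index_series`: `times`, `stable`,
#'   `dynamic`, `n_eligible`.
#' @export
stable_dynamic_index <- function(maps, window_ms = 310, guard_ms = 50) {
  stopifnot(inherits(maps, "significance_maps"))
  times <- maps$times
  S <- length(times)
  eps <- 1e-9
  lag <- abs(outer(times, times, "-"))
  eligible <- lag > guard_ms / 1000 + eps
  stableM <- (maps$class == "stable") & eligible
  dynamicM <- (maps$class == "dynamic") & eligible
  stableM[is.na(stableM)] <- FALSE
  dynamicM[is.na(dynamicM)] <- FALSE
  half <- window_ms / 2000
  stable <- dynamic <- numeric(S)
  n_elig <- integer(S)
  for (c in seq_len(S)) {
    sel <- which(abs(times - times[c]) <= half + eps)
    n_elig[c] <- sum(eligible[sel, sel])
    if (n_elig[c] == 0) {
      stable[c] <- NA_real_; dynamic[c] <- NA_real_
    } else {
      stable[c] <- sum(stableM[sel, sel]) / n_elig[c]
      dynamic[c] <- sum(dynamicM[sel, sel]) / n_elig[c]
    }
  }
  if (all(n_elig == 0))
    stop("guard excludes every cell of the window (window smaller ",
         "than guard)")
  structure(list(times = times, stable = stable, dynamic = dynamic,
                 n_eligible = n_elig, window_ms = window_ms,
                 guard_ms = guard_ms),
            class = "sd_index_series")
}

#' @export
print.sd_index_series <- function(x, ...) {
  cat("Stable/dynamic index series (", x$window_ms, " ms window, +/-",
      x$guard_ms, " ms guard)\n", sep = "")
  cat("stable:  mean", format(mean(x$stable, na.rm = TRUE), digits = 3),
      " max", format(max(x$stable, na.rm = TRUE), digits = 3), "\n")
  cat("dynamic: mean", format(mean(x$dynamic, na.rm = TRUE), digits = 3),
      " max", format(max(x$dynamic, na.rm = TRUE), digits = 3), "\n")
  invisible(x)
}

#' @export
as.data.frame.sd_index_series <- function(x, ...) {
  data.frame(time = x$times, stable = x$stable, dynamic = x$dynamic,
             n_eligible = x$n_eligible)
}
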