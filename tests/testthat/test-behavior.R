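test_that("orientation similarity is the stated linear map", {
  expect_equal(orientation_similarity(0), 1)
  expect_equal(orientation_similarity(c(-pi / 2, pi / 2)), c(0, 0))
  expect_equal(orientation_similarity(pi / 4), 0.5)
  expect_error(orientation_similarity(2), "wrap")
})

test_that("the cumulative Weibull hits its asymptotes and threshold
           semantics", {
  expect_equal(weibull_cdf(0, 0.4, 3, 0.9, 0.1), 0.1)     # e^0 = 1
  # at sim = alpha the function sits at 1 - 1/e of its amplitude
  w_at_alpha <- weibull_cdf(0.4, 0.4, 3, 0.9, 0.1)
  expect_equal((w_at_alpha - 0.1) / (0.9 - 0.1), 1 - exp(-1))
  # steep slope below threshold collapses to the lower asymptote
  expect_equal(weibull_cdf(0.3, 0.4, 80, 0.9, 0.1), 0.1,
               tolerance = 1e-8)
  expect_error(weibull_cdf(0.5, -1, 3, 0.9, 0.1), "alpha")
  # monotone in sim when gamma > delta
  s <- seq(0, 1, by = 0.05)
  expect_true(all(diff(weibull_cdf(s, 0.4, 3, 0.9, 0.1)) > 0))
})

test_that("Weibull MLE recovers generating parameters and is
           reproducible", {
  fits <- lapply(1:8, function(r)
    fit_weibull_mle(weibull_observer_table(0.4, 3, 0.9, 0.1, seed = r),
                    seed = r))
  est <- sapply(fits, function(f) c(f$alpha, f$beta, f$gamma, f$delta))
  bias <- rowMeans(est) - c(0.4, 3, 0.9, 0.1)
  expect_lt(abs(bias[1]), 0.05)
  expect_lt(abs(bias[2]), 0.5)
  expect_lt(abs(bias[3]), 0.05)
  expect_lt(abs(bias[4]), 0.05)
  tab <- weibull_observer_table(0.4, 3, 0.9, 0.1, seed = 9)
  expect_equal(fit_weibull_mle(tab, seed = 5)$nll,
               fit_weibull_mle(tab, seed = 5)$nll)
  # the fitted NLL beats perturbed parameter sets on average
  f <- fit_weibull_mle(tab, seed = 5)
  lev <- f$levels
  nll <- function(p) enscode:::.weibull_nll(p, lev$n, lev$k, lev$sim)
  set.seed(10)
  worse <- replicate(20, nll(pmin(pmax(
    c(f$alpha, f$beta, f$gamma, f$delta) + rnorm(4, 0, 0.05),
    1e-4), c(1, 100, 1, 1) - 1e-4)))
  expect_true(mean(worse >= f$nll - 1e-9) > 0.9)
})

test_that("degenerate old/new tables drive the asymptotes to the
           boundary", {
  offs <- rep(probe_offsets_oldnew("VO"), each = 5)
  all_old <- data.frame(probe_offset_deg = offs, response = "old")
  f <- fit_weibull_mle(all_old, n_restarts = 10, seed = 11)
  expect_true(f$boundary)
  expect_gt(f$gamma, 0.99)
  expect_gt(f$delta, 0.99)
  expect_error(fit_weibull_mle(all_old[0, ]), "empty")
  one_level <- data.frame(probe_offset_deg = 0,
                          response = c("old", "new"))
  expect_error(fit_weibull_mle(one_level), "similarity levels")
})

test_that("old/new tuning curve reports proportions and missing bins", {
  tab <- data.frame(probe_offset_deg = c(rep(0, 10), rep(20, 4)),
                    response = c(rep("old", 10), rep("new", 2),
                                 rep("old", 2)))
  cur <- oldnew_tuning_curve(tab, offsets = c(0, 20, 40))
  expect_equal(cur$prop_old[cur$probe_offset_deg == 0], 1.0)
  expect_equal(cur$prop_old[cur$probe_offset_deg == 20], 0.5)
  expect_true(is.na(cur$prop_old[cur$probe_offset_deg == 40]))
  # pooled comparison statistic at 0 vs the item offsets is computable
  pooled <- with(oldnew_tuning_curve(tab),
                 sum(k[probe_offset_deg != 0]) /
                   sum(n[probe_offset_deg != 0]))
  expect_equal(pooled, 0.5)
})

test_that("estimation bias uses the toward-mean sign convention and
           recovers the generator's w", {
  # constructed: -5 deg error at target +22.5 and +5 at -22.5 are both
  # 5 deg toward the mean
  tab <- data.frame(target_offset_deg = rep(c(22.5, -22.5), each = 6),
                    response_error_deg = rep(c(-5, 5), each = 6),
                    split_label = "unassigned")
  b <- estimation_bias(tab)
  expect_equal(b$per_target$bias_toward_mean_deg, c(5, 5))
  expect_equal(b$tendency, 5)
  # symmetric zero-mean errors -> bias near 0 at every target
  set.seed(12)
  tab0 <- data.frame(
    target_offset_deg = sample(c(-22.5, -7.5, 7.5, 22.5), 4000,
                               replace = TRUE),
    response_error_deg = rnorm(4000, 0, 8))
  expect_lt(max(abs(estimation_bias(tab0)$per_target$bias_toward_mean_deg)),
            1)
  # generator round trip: tendency = w * mean(|offsets|)
  stim <- generate_stimuli(10000, "VO", 2, seed = 13)
  tb <- simulate_estimation_behavior(stim, w = 0.4, kappa = 15,
                                     seed = 14)
  expect_equal(estimation_bias(tb)$tendency, 0.4 * 15, tolerance = 0.5)
  expect_error(estimation_bias(tb[tb$target_offset_deg > 0, ]),
               NA)   # fewer levels is fine as long as each is present
})

test_that("estimation bias is equivariant under rotation of responses", {
  set.seed(15)
  tab <- data.frame(
    target_offset_deg = rep(c(-22.5, -7.5, 7.5, 22.5), each = 50),
    response_error_deg = rnorm(200, 0, 6))
  shifted <- tab
  shifted$response_error_deg <- wrap_orientation(
    tab$response_error_deg + 3)
  b0 <- estimation_bias(tab)$per_target$bias_toward_mean_deg
  b1 <- estimation_bias(shifted)$per_target$bias_toward_mean_deg
  sgn <- -sign(c(-22.5, -7.5, 7.5, 22.5))
  expect_equal(b1 - b0, sgn * 3, tolerance = 1e-6)
})

test_that("precision is reciprocal circular SD with a closed-form
           check", {
  kappa <- 12
  set.seed(16)
  tab <- data.frame(target_offset_deg = 7.5,
                    response_error_deg = rvm_orientation(10000, 0, kappa))
  p <- estimation_precision(tab)
  rbar <- besselI(kappa, 1) / besselI(kappa, 0)
  sd_closed <- sqrt(-2 * log(rbar)) / 2 * 180 / pi
  expect_equal(p$precision, 1 / sd_closed, tolerance = 0.05)
  # doubling the circular SD roughly halves precision
  set.seed(17)
  wide <- data.frame(target_offset_deg = 7.5,
                     response_error_deg = rvm_orientation(10000, 0, 3.1))
  expect_equal(p$precision / estimation_precision(wide)$precision, 2,
               tolerance = 0.2)
  expect_warning(prec0 <- estimation_precision(
    data.frame(target_offset_deg = 1, response_error_deg = c(4, 4))),
    "infinite")
  expect_true(prec0$infinite)
})

test_that("median split partitions deterministically with ties to
           'mean'", {
  # bimodal: half exactly toward-mean by 20, half at 0
  tab <- data.frame(target_offset_deg = rep(22.5, 20),
                    response_error_deg = rep(c(0, -20), each = 10),
                    split_label = "unassigned")
  sp <- median_split(tab)
  expect_equal(sum(sp$split_label == "mean"), 10)
  expect_equal(sp$split_label[tab$response_error_deg == -20],
               rep("mean", 10))
  expect_equal(sp$split_label[tab$response_error_deg == 0],
               rep("target", 10))
  # symmetric sample: group sizes differ by at most 1 (ties to "mean")
  set.seed(18)
  tb <- data.frame(target_offset_deg = rep(c(-7.5, 7.5), 100),
                   response_error_deg = rnorm(200, 2, 5),
                   split_label = "unassigned")
  sp2 <- median_split(tb)
  expect_lte(abs(sum(sp2$split_label == "mean") -
                   sum(sp2$split_label == "target")), 1)
  # labels do not depend on trial order
  perm <- sample(nrow(tb))
  sp3 <- median_split(tb[perm, ])
  expect_equal(sp3$split_label, sp2$split_label[perm])
  # degenerate and tiny inputs are refused
  expect_error(median_split(tb[1:3, ]), "4 trials")
  same <- data.frame(target_offset_deg = 7.5,
                     response_error_deg = rep(2, 10),
                     split_label = "unassigned")
  expect_error(median_split(same), "degenerate")
})
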