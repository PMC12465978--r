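test_that("MSD matches analytic ballistic and immobile cases", {
  # p(t_m) = (m, 0), dt = 1: MSD(k) = k^2
  tr <- locus_trajectory(0:20, cbind(0:20, 0))
  msd <- compute_msd(tr)
  expect_equal(msd$msd, (1:20)^2)
  expect_equal(msd$n_pairs, 20:1)

  const <- locus_trajectory(0:10, cbind(rep(1, 11), rep(-2, 11)))
  expect_true(all(compute_msd(const)$msd == 0))
})

test_that("MSD equals the brute-force double loop and uses overlapping windows", {
  set.seed(21)
  pos <- matrix(cumsum(rnorm(100, sd = 0.1)), 50, 2)
  tr <- locus_trajectory(seq(0, by = 0.2, length.out = 50), pos)
  msd <- compute_msd(tr)
  expect_equal(msd$msd, brute_msd(pos, 0.2, 49), tolerance = 1e-9)
  expect_equal(msd$n_pairs, 49:1)

  # the non-overlapping (stride-k) estimator is a different statistic
  k <- 5
  stride_idx <- seq(1, 50, by = k)
  stride_msd <- mean(rowSums(
    (pos[stride_idx[-1], ] - pos[stride_idx[-length(stride_idx)], ])^2))
  expect_false(isTRUE(all.equal(stride_msd, msd$msd[k])))
})

test_that("drift correction inverts injected drift exactly and is idempotent", {
  set.seed(31)
  base <- matrix(cumsum(rnorm(60, sd = 0.05)), 30, 2)
  t <- seq(0, by = 0.2, length.out = 30)
  drift <- outer(0:29, c(0.03, -0.01))

  # constant centroid: output equals input
  tr0 <- locus_trajectory(t, base, centroid = matrix(1, 30, 2))
  expect_equal(drift_correct(tr0)$pos, base)

  # injected drift with matching centroid series: exact inversion
  tr <- locus_trajectory(t, base + drift, centroid = drift)
  corr <- drift_correct(tr)
  expect_equal(corr$pos, base, tolerance = 1e-12)
  expect_equal(drift_correct(corr)$pos, corr$pos)
  expect_equal(corr$pos[1, ], (base + drift)[1, ])  # first frame unchanged

  expect_error(drift_correct(locus_trajectory(t, base)), "centroid")
})

test_that("uncorrected drift inflates long-lag MSD quadratically", {
  trs_d <- generate_trajectories(200, D_true = 0.005, alpha_true = 1,
                                 drift_per_frame = c(0.05, 0), seed = 41)
  msd_raw <- rowMeans(sapply(trs_d, function(tr) compute_msd(tr)$msd))
  k <- seq_along(msd_raw)
  # drift term (0.05 um/frame)^2 k^2 dominates at long lags
  expect_gt(msd_raw[80] / msd_raw[20], 10)
  msd_corr <- rowMeans(sapply(trs_d, function(tr)
    compute_msd(drift_correct(tr))$msd))
  trs_f <- generate_trajectories(200, D_true = 0.005, alpha_true = 1,
                                 seed = 41)
  msd_free <- rowMeans(sapply(trs_f, function(tr) compute_msd(tr)$msd))
  expect_equal(msd_corr, msd_free, tolerance = 1e-10)
})

test_that("power-law fits are exact on exact power laws", {
  lag <- (1:25) * 0.2
  mk <- function(vals, n) structure(
    data.frame(lag_s = lag, msd = vals, n_pairs = n - seq_along(lag) + 1),
    dt = 0.2, n = n, class = c("msd_curve", "data.frame"))

  pl <- fit_power_law(mk(4 * 0.05 * lag^0.7, 99))
  expect_equal(pl$alpha, 0.7, tolerance = 1e-12)
  expect_equal(pl$D_app, 0.05, tolerance = 1e-12)
  expect_equal(pl$r_squared, 1, tolerance = 1e-9)

  pl2 <- fit_power_law(mk(4 * 0.02 * lag, 99))
  expect_equal(pl2$alpha, 1, tolerance = 1e-12)
  expect_equal(pl2$D_app, 0.02, tolerance = 1e-12)
  expect_equal(unname(coef(pl2)), c(0.02, 1), tolerance = 1e-9)

  expect_error(fit_power_law(mk(rep(0, 25), 99)), "fit error")
})

test_that("trajectory gyration radius matches analytic and brute-force values", {
  expect_equal(trajectory_radius(matrix(c(3, -1), 1, 2)), 0)
  expect_equal(trajectory_radius(rbind(c(0, 0), c(3, 4))), 2.5)  # d/2

  set.seed(51)
  pos <- matrix(rnorm(200), 100, 2)
  ctr <- c(mean(pos[, 1]), mean(pos[, 2]))
  brute <- sqrt(sum((pos[, 1] - ctr[1])^2 + (pos[, 2] - ctr[2])^2) / 100)
  expect_equal(trajectory_radius(pos), brute, tolerance = 1e-12)

  # translation/rotation invariant, scales linearly
  r0 <- trajectory_radius(pos)
  expect_equal(trajectory_radius(random_similarity(pos)), r0,
               tolerance = 1e-9)
  expect_equal(trajectory_radius(pos * 3), 3 * r0, tolerance = 1e-12)
})

test_that("effective diffusion is the through-origin short-lag slope", {
  lag <- (1:10) * 0.2
  msd <- structure(
    data.frame(lag_s = lag, msd = 0.4 * lag, n_pairs = 10:1),
    dt = 0.2, n = 10, class = c("msd_curve", "data.frame"))
  expect_equal(effective_diffusion(msd), 0.1, tolerance = 1e-12)

  const <- locus_trajectory(0:5, cbind(rep(0, 6), rep(0, 6)))
  expect_equal(effective_diffusion(compute_msd(const)), 0)

  short <- locus_trajectory(0:2, cbind(0:2, 0))
  expect_error(effective_diffusion(compute_msd(short)), "lags 1-3")
})

test_that("Brownian ensembles recover D through every estimator", {
  trs <- generate_trajectories(400, D_true = 0.01, alpha_true = 1,
                               n_frames = 100, dt = 0.2, seed = 61)
  msd1 <- sapply(trs, function(tr) compute_msd(tr, k_max = 3)$msd[1])
  se <- sd(msd1) / sqrt(length(msd1))
  expect_lt(abs(mean(msd1) - 4 * 0.01 * 0.2), 3 * se)

  deff <- sapply(trs, function(tr) effective_diffusion(compute_msd(tr, 3)))
  expect_lt(abs(mean(deff) - 0.01), 3 * sd(deff) / sqrt(length(deff)))
})

test_that("Welch test matches the textbook formula and its conventions", {
  set.seed(71)
  a <- rnorm(15, 1, 2); b <- rnorm(25, 1.8, 0.5)
  got <- welch_test(a, b)
  want <- brute_welch(a, b)
  expect_equal(got$t, want$t, tolerance = 1e-12)
  expect_equal(got$dof, want$dof, tolerance = 1e-9)
  expect_equal(got$p_two_sided, want$p, tolerance = 1e-12)

  same <- welch_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_two_sided, 1)

  sep <- welch_test(c(1, 2, 3), c(101, 102, 103))
  expect_lt(sep$p_two_sided, 0.01)

  expect_equal(welch_test(c(2, 2, 2), c(2, 2))$p_two_sided, 1)
  expect_error(welch_test(c(2, 2, 2), c(3, 3)), "degenerate")
  expect_error(welch_test(1, c(1, 2)), "at least 2")
})
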