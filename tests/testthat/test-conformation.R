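test_that("EM recovers the generating mixture and agrees with the histogram fit", {
  k <- generate_k_sample(1e4, seed = 101)
  em <- fit_bimodal(k, method = "em", seed = 1)
  expect_true(em$converged)
  expect_false(em$overlap_flag)
  expect_lt(abs(em$mu_c - 1.82), 0.05)
  expect_lt(abs(em$mu_e - 3.58), 0.05)
  expect_lt(abs(em$w_e - 0.81), 0.03)

  hl <- fit_bimodal(k, method = "histogram_ls")
  expect_lt(abs(hl$mu_c - em$mu_c), 0.1)
  expect_lt(abs(hl$mu_e - em$mu_e), 0.1)
  expect_lt(abs(hl$w_e - em$w_e), 0.05)
})

test_that("EM agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))
  k <- generate_k_sample(3000, seed = 55)
  em <- fit_bimodal(k, seed = 2)
  mc <- Mclust(k, G = 2, modelNames = "V", verbose = FALSE)
  mu_mc <- sort(mc$parameters$mean)
  expect_lt(abs(em$mu_c - mu_mc[1]), 0.05)
  expect_lt(abs(em$mu_e - mu_mc[2]), 0.05)
  expect_lt(abs(em$loglik - mc$loglik), 1)
})

test_that("EM log-likelihood is non-decreasing across iterations", {
  k <- generate_k_sample(2000, seed = 77)
  fit <- fit_bimodal(k, seed = 3)
  expect_true(all(diff(fit$loglik_trace) > -1e-9))
})

test_that("identical components are overlap-flagged and refuse percentages", {
  set.seed(9)
  k <- pmax(rnorm(500, 2.5, 0.4), 1)
  fit <- fit_bimodal(k, seed = 1)
  expect_true(fit$overlap_flag)
  expect_error(conformation_percentages(fit), "overlap")
})

test_that("component relabeling is symmetric: mu_c < mu_e always", {
  for (s in 1:5) {
    k <- generate_k_sample(500, w_extended = runif(1, 0.2, 0.8), seed = s)
    fit <- fit_bimodal(k, seed = s)
    expect_lt(fit$mu_c, fit$mu_e)
    expect_gte(fit$w_e, 0)
    expect_lte(fit$w_e, 1)
  }
})

test_that("insufficient samples are rejected", {
  expect_error(fit_bimodal(rep(2, 10)), "insufficient")
})

test_that("percentages are the mixture weights", {
  fit <- fit_bimodal(generate_k_sample(5000, seed = 1), seed = 1)
  fit$w_e <- 0.81
  expect_equal(unname(conformation_percentages(fit)), c(81, 19))
  fit$w_e <- 0.31
  expect_equal(unname(conformation_percentages(fit)), c(31, 69))
  fit$w_e <- 0
  expect_equal(unname(conformation_percentages(fit)), c(0, 100))
})

test_that("classification thresholds at the posterior crossing", {
  fit <- fit_bimodal(generate_k_sample(5000, seed = 2), seed = 1)
  expect_identical(classify_territory(fit$mu_e, fit), "extended")
  expect_identical(classify_territory(fit$mu_c, fit), "collapsed")
  expect_identical(classify_territory(Inf, fit), "extended")

  # equal weights and sigmas: threshold is the midpoint of the means
  fit$w_e <- 0.5
  fit$sigma_c <- fit$sigma_e <- 0.4
  thr <- territoryshape:::posterior_threshold(
    c(fit$mu_c, fit$mu_e), c(0.4, 0.4), c(0.5, 0.5))
  expect_equal(thr, (fit$mu_c + fit$mu_e) / 2, tolerance = 1e-8)
  expect_identical(predict(fit, thr + 1e-6), "extended")
  expect_identical(predict(fit, thr - 1e-6), "collapsed")
})

test_that("mixture fit objects support the standard model methods", {
  k <- generate_k_sample(1000, seed = 4)
  fit <- fit_bimodal(k, seed = 1)
  expect_named(coef(fit), c("mu_c", "mu_e", "sigma_c", "sigma_e", "w_e"))
  expect_s3_class(logLik(fit), "logLik")
  expect_output(print(fit), "Bimodal Gaussian fit")
  sim <- simulate(fit, nsim = 50, seed = 3)
  expect_length(sim, 50)
  expect_true(all(sim >= 1))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("Fisher comparison reproduces the reference contrast and edge cases", {
  # 81% extended of 104 vs 31% of 100 (reconstructed counts)
  res <- compare_conditions(c(n_extended = 84, n_collapsed = 20),
                            c(n_extended = 31, n_collapsed = 69))
  expect_lt(res$p_two_sided, 0.001)
  expect_gt(res$odds_ratio, 1)

  flat <- compare_conditions(c(n_extended = 1, n_collapsed = 1),
                             c(n_extended = 1, n_collapsed = 1))
  expect_equal(flat$p_two_sided, 1)

  expect_error(compare_conditions(c(n_extended = 0, n_collapsed = 0),
                                  c(n_extended = 3, n_collapsed = 4)),
               "margin")
})

test_that("Fisher p is invariant under simultaneous row and column swaps", {
  set.seed(12)
  for (rep in 1:20) {
    a <- c(n_extended = rpois(1, 20) + 1, n_collapsed = rpois(1, 20) + 1)
    b <- c(n_extended = rpois(1, 20) + 1, n_collapsed = rpois(1, 20) + 1)
    p1 <- compare_conditions(a, b)$p_two_sided
    p2 <- compare_conditions(c(n_extended = unname(b["n_collapsed"]),
                               n_collapsed = unname(b["n_extended"])),
                             c(n_extended = unname(a["n_collapsed"]),
                               n_collapsed = unname(a["n_extended"])))$p_two_sided
    expect_equal(p1, p2, tolerance = 1e-12)
    expect_gt(p1, 0)
    expect_lte(p1, 1)
  }
})
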