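test_that("territory curves have exact spacing and are deterministic in the seed", {
  crv <- generate_territory_curve(n_points = 150, step_len = 0.07, seed = 5)
  expect_equal(nrow(crv$points), 150)
  seg <- sqrt(rowSums(diff(crv$points)^2))
  expect_equal(seg, rep(0.07, 149), tolerance = 1e-12)
  crv2 <- generate_territory_curve(n_points = 150, step_len = 0.07, seed = 5)
  expect_identical(crv$points, crv2$points)
  crv3 <- generate_territory_curve(n_points = 150, step_len = 0.07, seed = 6)
  expect_false(identical(crv$points, crv3$points))

  expect_error(generate_territory_curve(n_points = 2), "n_points")
  expect_error(generate_territory_curve(step_len = 0), "step_len")
  expect_error(generate_territory_curve(persistence = -1), "persistence")
})

test_that("infinite persistence gives a straight chain flagged infinite-K", {
  crv <- generate_territory_curve(persistence = Inf, seed = 1)
  expect_true(gyration_tensor(crv$points)$infinite_K)
})

test_that("stiffer chains are more extended: K grows with persistence", {
  k_of <- function(pers, seeds) {
    sapply(seeds, function(s) {
      shape_from_curve(generate_territory_curve(persistence = pers,
                                                seed = s))$K
    })
  }
  seeds <- 1:200
  grid <- c(0, 2, 10, 25, 50)
  med <- sapply(grid, function(p) median(k_of(p, seeds)))
  expect_gt(mean(k_of(50, 1:500)), mean(k_of(0, 1:500)))
  expect_gt(cor(grid, med, method = "spearman"), 0.9)
})

test_that("K mixture samples hit the specified moments and truncation", {
  # single extended component anchored at the OB extended mode
  k <- generate_k_sample(1e5, w_extended = 1, mu_extended = 3.58,
                         sigma_extended = 0.4, seed = 2)
  expect_lt(abs(mean(k) - 3.58), 0.02)  # 3 SE is ~0.004; spec'd band 0.02
  expect_true(all(k >= 1))

  # full mixture: mean within 3 SE of the mixture mean
  k2 <- generate_k_sample(1e5, seed = 3)
  mix_mean <- 0.81 * 3.58 + 0.19 * 1.82
  mix_var <- 0.81 * (0.6^2 + 3.58^2) + 0.19 * (0.3^2 + 1.82^2) - mix_mean^2
  expect_lt(abs(mean(k2) - mix_mean), 3 * sqrt(mix_var / 1e5) + 0.01)

  # strong truncation: all draws still >= 1 by redraw, not clipping
  k3 <- generate_k_sample(2e4, mu_collapsed = 1.05, sigma_collapsed = 0.5,
                          w_extended = 0, mu_extended = 3, seed = 4)
  expect_true(all(k3 >= 1))
  expect_lt(mean(k3 < 1.001), 0.01)  # no pile-up at the boundary

  expect_identical(generate_k_sample(1e4, seed = 9),
                   generate_k_sample(1e4, seed = 9))
  expect_false(identical(as.numeric(generate_k_sample(1e4, seed = 9)),
                         as.numeric(generate_k_sample(1e4, seed = 10))))
  expect_error(generate_k_sample(0), "positive")
})

test_that("fBM trajectories are deterministic, sized and validated", {
  tr <- generate_trajectory(D_true = 0.01, alpha_true = 1, n_frames = 100,
                            dt = 0.2, seed = 8)
  expect_s3_class(tr, "locus_trajectory")
  expect_equal(tr$n, 99)
  expect_equal(tr$t, (0:99) * 0.2)
  tr2 <- generate_trajectory(D_true = 0.01, alpha_true = 1, n_frames = 100,
                             dt = 0.2, seed = 8)
  expect_identical(tr$pos, tr2$pos)

  # minimal size: 2 frames, MSD defined at lag 1 only
  tr3 <- generate_trajectory(D_true = 0.01, alpha_true = 1, n_frames = 2,
                             seed = 1)
  msd <- compute_msd(tr3)
  expect_equal(nrow(msd), 1)
  expect_error(compute_msd(tr3, k_max = 2), "k_max")

  expect_error(generate_trajectory(0.01, alpha_true = 2.2), "alpha_true")
  expect_error(generate_trajectory(0.01, alpha_true = 0), "alpha_true")
})

test_that("the nuclear-centroid series equals the injected drift exactly", {
  tr <- generate_trajectory(D_true = 0.02, alpha_true = 0.8,
                            drift_per_frame = c(0.05, -0.02), seed = 12)
  expect_equal(tr$centroid, outer(0:99, c(0.05, -0.02)))
  corr <- drift_correct(tr)
  free <- generate_trajectory(D_true = 0.02, alpha_true = 0.8, seed = 12)
  expect_equal(corr$pos, free$pos, tolerance = 1e-12)
})

test_that("confined trajectories stay within the reflecting radius", {
  trs <- generate_trajectories(20, D_true = 0.05, alpha_true = 1,
                               confinement_radius = 0.3, seed = 5)
  for (tr in trs) {
    expect_true(all(sqrt(rowSums(tr$pos^2)) <= 0.3 + 1e-9))
  }
})

test_that("rendered stacks are deterministic and localize spots on the curve", {
  crv <- generate_territory_curve(mode = "extended", seed = 21)
  st <- generate_image_stack(crv, seed = 21)
  st2 <- generate_image_stack(crv, seed = 21)
  expect_identical(st$voxels, st2$voxels)
  expect_equal(dim(st$voxels)[1], 10)

  # noise-free limit: bright pixels lie within 1 px of the true curve
  hi <- generate_image_stack(crv, photons_per_spot = 1e6, background = 0,
                             seed = 1)
  img <- max_intensity_project(hi)
  tc <- attr(hi, "truth_curve")$points
  bright <- which(img$pixels > 0.5 * max(img$pixels), arr.ind = TRUE)
  xy <- cbind((bright[, 2] - 0.5), (bright[, 1] - 0.5)) * hi$pixel_size
  d <- apply(xy, 1, function(q) min(sqrt(colSums((t(tc) - q)^2))))
  expect_lt(max(d), 2 * hi$pixel_size)

  # background only: segmentation returns no territory
  dark <- generate_image_stack(crv, photons_per_spot = 0, background = 5,
                               seed = 2)
  msk <- segment_territory(max_intensity_project(dark))
  expect_true(isTRUE(attr(msk, "empty")))
  expect_equal(territory_area(msk), 0)
})
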