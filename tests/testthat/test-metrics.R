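# Outcome measures: analytic oracles and invariances.

test_that("rmse matches hand computations", {
  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(2, 2, 2), c(0, 2, 4)), sqrt(8 / 3))
  expect_equal(rmse(3, 1), 2)
  expect_error(rmse(1:3, 1:4), class = "imu2grf_length_mismatch")
})

test_that("pearson_rho handles affine, inverted, and orthogonal cases", {
  ref <- c(1, 3, 2, 5, 4)
  expect_equal(pearson_rho(2 * ref + 1, ref), 1)
  expect_equal(pearson_rho(-ref, ref), -1)
  expect_equal(pearson_rho(c(1, 2, 3, 4), c(1, 2, 2, 1)), 0)
  expect_error(pearson_rho(rep(1, 5), ref), class = "imu2grf_constant_sequence")
  expect_error(pearson_rho(1:2, 1:2), class = "imu2grf_length_mismatch")
})

test_that("fisher_mean_rho averages on the z scale", {
  expect_equal(fisher_mean_rho(c(0.8, 0.8)), 0.8)
  expect_equal(fisher_mean_rho(c(0, 0.8)), 0.5)   # tanh(ln(3)/2) = 1/2
  expect_equal(fisher_mean_rho(0.37), 0.37)
  expect_equal(fisher_mean_rho(c(1, 1)), 1, tolerance = 1e-9)
  set.seed(9)
  rhos <- runif(20, -0.9, 0.9)
  fm <- fisher_mean_rho(rhos)
  expect_gte(fm, min(rhos)); expect_lte(fm, max(rhos))
  expect_error(fisher_mean_rho(numeric(0)), class = "imu2grf_empty")
})

test_that("stance-wise discrete outcomes follow their definitions", {
  angles <- tibble::tibble(left_knee = rep(30, 100), right_knee = rep(10, 100))
  st <- tibble::tibble(side = "left", start = 20L, end = 50L, t_contact = 20 / 120)
  expect_equal(max_knee_flexion_stance(angles, st), 30)
  tri <- angles
  tri$left_knee[35] <- 41
  expect_equal(max_knee_flexion_stance(tri, st), 41)
  expect_error(max_knee_flexion_stance(angles[, "right_knee"], st),
               class = "imu2grf_schema")

  vgrf <- rep(0, 100); vgrf[20:49] <- seq(100, 2060.1, length.out = 30)
  expect_equal(peak_vgrf_bw(vgrf, st, mass = 70), 3.0, tolerance = 1e-4)
  expect_equal(peak_vgrf_bw(rep(686.7, 100), st, 70), 1.0, tolerance = 1e-4)
  expect_equal(peak_vgrf_bw(rep(0, 100), st, 70), 0)
})

test_that("the passive-peak time picks the dominant early-stance transient", {
  fs <- 1000
  st <- tibble::tibble(side = "left", start = 101L, end = 351L,
                       t_contact = 0.1)   # 250 ms stance
  acc <- rep(0, 500)
  acc[101 + 25] <- 50                     # impulse 25 ms after contact
  expect_equal(passive_peak_time(acc, st, fs), 0.025)
  acc[101 + 100] <- 30                    # later, smaller
  expect_equal(passive_peak_time(acc, st, fs), 0.025)
  acc[101 + 20] <- -80                    # larger magnitude, negative
  expect_equal(passive_peak_time(acc, st, fs), 0.020)
  expect_error(passive_peak_time(acc, tibble::tibble(side = "l", start = 1L,
                                                     end = 3L), fs),
               class = "imu2grf_bounds")
})

test_that("loading rate equals the slope of an affine ramp in BW/s", {
  fs <- 1000
  st <- tibble::tibble(side = "left", start = 1L, end = 301L, t_contact = 0)
  ramp <- 5000 * seq(0, 0.999, by = 1 / fs)   # F(t) = 5000 t, F(0) = 0
  lr <- loading_rate(ramp, fs, st, t_pp = 0.03, mass = 70)
  expect_equal(lr, 5000 / (70 * 9.81), tolerance = 1e-9)
  expect_equal(lr, 7.28, tolerance = 1e-3)
  # slope independence of t_pp and fs for affine signals
  expect_equal(loading_rate(ramp, fs, st, t_pp = 0.12, mass = 70), lr)
  st2 <- tibble::tibble(side = "left", start = 1L, end = 31L, t_contact = 0)
  ramp2 <- 5000 * seq(0, 0.29, by = 1 / 100)
  expect_equal(loading_rate(ramp2, 100, st2, t_pp = 0.12, mass = 70), lr,
               tolerance = 1e-9)
  expect_equal(loading_rate(rep(500, 301), fs, st, 0.03, 70), 0)
  expect_error(loading_rate(ramp, fs, st, t_pp = 1e-4, mass = 70),
               class = "imu2grf_bounds")
})

test_that("Bland-Altman bias and limits of agreement are the classic formulas", {
  same <- c(1, 2, 3)
  ba <- bland_altman(same, same)
  expect_equal(ba$bias, 0); expect_equal(ba$loa_low, 0); expect_equal(ba$loa_high, 0)
  ba2 <- bland_altman(c(1, -1, 0) + 5, c(5, 5, 5))
  expect_equal(ba2$bias, 0)
  expect_equal(ba2$loa_high, 1.96)
  expect_equal(ba2$loa_low, -1.96)
  ba3 <- bland_altman(c(4, 5, 6), c(1, 2, 3))
  expect_equal(ba3$bias, 3); expect_equal(ba3$loa_low, 3); expect_equal(ba3$loa_high, 3)
  # coverage on a large Gaussian simulation: LoA contain >= 90% of differences
  set.seed(10)
  est <- rnorm(2000); ref <- rnorm(2000)
  ba4 <- bland_altman(est, ref)
  d <- est - ref
  expect_gte(mean(d >= ba4$loa_low & d <= ba4$loa_high), 0.90)
})

test_that("the paired t-test flags shifts and stays calm under the null", {
  set.seed(11)
  ref <- rnorm(100)
  shifted <- paired_ttest(ref + 1 + rnorm(100, 0, 0.01), ref)
  expect_true(shifted$significant)
  null <- paired_ttest(ref + rnorm(100), ref)
  expect_gt(null$p, 0.05)
  tt <- paired_ttest(c(1, 0), c(0, 1))
  expect_equal(tt$t, 0); expect_equal(tt$p, 1)
  degen <- paired_ttest(c(1, 2, 3), c(0, 1, 2))
  expect_true(degen$degenerate)
  expect_false(degen$significant)
})

test_that("agreement summaries aggregate per-segment scores", {
  seg <- list(c(1, 2, 3, 4), c(2, 1, 4, 3))
  out <- summarize_agreement(seg, seg)
  expect_equal(out$rho_mean, 1, tolerance = 1e-9)
  expect_equal(out$rmse_mean, 0)
  expect_equal(out$rmse_sd, 0)
  expect_equal(out$n_segments, 2L)
  # rmse aggregation: segments with RMSE 1 and 3
  est <- list(c(1, 2, 3, 4) + 1, c(1, 2, 3, 4) + 3)
  ref <- list(c(1, 2, 3, 4), c(1, 2, 3, 4))
  out2 <- summarize_agreement(est, ref)
  expect_equal(out2$rmse_mean, 2)
  expect_equal(out2$rmse_sd, sqrt(2), tolerance = 1e-9)
  expect_error(summarize_agreement(est, ref[1]), class = "imu2grf_length_mismatch")
  expect_error(summarize_agreement(list(), list()), class = "imu2grf_empty")
})

test_that("metrics are invariant to a common time shift", {
  set.seed(12)
  est <- rnorm(50); ref <- rnorm(50)
  expect_equal(rmse(est, ref), rmse(c(est, est), c(ref, ref)))
  expect_equal(pearson_rho(est, ref), pearson_rho(rev(est), rev(ref)))
})
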