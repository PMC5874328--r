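# The function-fitting networks and the concatenated estimator.

test_that("training solves an identity task and predicts it back", {
  set.seed(3)
  X <- matrix(runif(2000 * 3, -1, 1), ncol = 3,
              dimnames = list(NULL, c("a", "b", "c")))
  Y <- cbind(y = X[, 2])
  m <- train_mlp(X, Y, tiny_config(seed = 2, maxit = 200))
  pred <- predict(m, X)
  expect_lt(sqrt(mean((pred - Y)^2)), 1e-2)
  # single row in, single row out; permuted rows give permuted outputs
  expect_equal(dim(predict(m, X[1, , drop = FALSE])), c(1L, 1L))
  perm <- sample(nrow(X))
  expect_equal(predict(m, X[perm, ]), pred[perm, , drop = FALSE])
})

test_that("degenerate constant targets stop early and predict the constant", {
  set.seed(4)
  X <- matrix(rnorm(300 * 2), ncol = 2)
  Y <- matrix(5, nrow = 300, ncol = 1)
  m <- train_mlp(X, Y, tiny_config(seed = 1, maxit = 100))
  expect_lt(m$iterations, 100)
  expect_equal(drop(predict(m, X)), rep(5, 300), tolerance = 1e-3)
})

test_that("training is bit-deterministic given a seed and guards bad input", {
  set.seed(5)
  X <- matrix(rnorm(400), 200, 2)
  Y <- cbind(X[, 1] + X[, 2]^2)
  m1 <- train_mlp(X, Y, tiny_config(seed = 7, maxit = 30))
  m2 <- train_mlp(X, Y, tiny_config(seed = 7, maxit = 30))
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$history, m2$history)
  m3 <- train_mlp(X, Y, tiny_config(seed = 8, maxit = 30))
  expect_false(identical(m1$weights, m3$weights))
  expect_error(train_mlp(X[1:50, ], Y[1:50, , drop = FALSE], tiny_config()),
               class = "imu2grf_too_few_samples")
  Xbad <- X; Xbad[3, 1] <- NA
  expect_error(train_mlp(Xbad, Y, tiny_config()), class = "imu2grf_nonfinite")
  expect_error(predict(m1, X[, 1, drop = FALSE]), class = "imu2grf_schema")
  colnames(X) <- c("wrong", "names")
  expect_error(predict(m1, X), class = "imu2grf_schema")
})

test_that("the training loss history is monotone non-increasing", {
  set.seed(6)
  X <- matrix(rnorm(600), 300, 2)
  Y <- cbind(sin(X[, 1]) + 0.5 * X[, 2])
  m <- train_mlp(X, Y, tiny_config(seed = 3, maxit = 120))
  expect_true(all(diff(m$history$loss) <= 1e-9))
  expect_equal(m$history$iteration, seq_len(m$iterations))
})

test_that("both stopping-rule readings terminate training", {
  set.seed(8)
  X <- matrix(rnorm(600), 300, 2)
  Y <- cbind(X[, 1])
  cfg_g <- tiny_config(seed = 2, maxit = 500)
  m_g <- train_mlp(X, Y, cfg_g)
  expect_true(m_g$stop_reason %in%
                c("gradient_patience", "grad_tolerance", "line_search_failure",
                  "max_iterations"))
  cfg_v <- train_config(hidden_sizes = c(24, 12), max_iterations = 500,
                        seed = 2, stop_rule = "validation")
  m_v <- train_mlp(X, Y, cfg_v)
  expect_true(m_v$stop_reason %in%
                c("validation_patience", "grad_tolerance",
                  "line_search_failure", "max_iterations"))
})

test_that("the concatenated estimator trains, estimates, and clips at zero", {
  ds <- small_dataset()
  trials <- ds$trial[ds$subject_id == ds$subject_id[1] & ds$speed != 12]
  est <- build_estimator(trials, scheme = "imu", feature_set = "a_pl_theta",
                         config = tiny_config(seed = 5, maxit = 60))
  expect_equal(est$ann1$dims$d_in, 8L)
  expect_equal(est$ann1$dims$d_out, 6L)
  expect_equal(est$ann2$dims$d_in, 9L)
  expect_equal(est$ann2$dims$d_out, 2L)
  test_trial <- ds$trial[ds$subject_id == ds$subject_id[1] & ds$speed == 12][[1]]
  out <- estimate(est, test_trial)
  expect_equal(nrow(out$angles), nrow(test_trial$data))
  expect_true(all(out$vgrf$vgrf_left >= 0))
  # deployment path works without force channels
  blind <- test_trial
  blind$data$vgrf_left <- NULL
  blind$data$vgrf_right <- NULL
  out2 <- estimate(est, blind)
  expect_equal(out2$angles, out$angles)
  expect_equal(names(out2), c("angles", "vgrf"))
  # missing IMU channels are a hard error
  broken <- test_trial
  broken$data$pelvis_qw <- NULL
  expect_error(estimate(est, broken), class = "imu2grf_missing_channels")
  expect_error(build_estimator(list(), config = tiny_config()),
               class = "imu2grf_no_trials")
})

test_that("the two schemes share force targets but differ in angle targets", {
  ds <- small_dataset()
  trials <- ds$trial[ds$subject_id == ds$subject_id[1] & ds$speed != 12]
  io_imu <- build_ann1_io(trials[[1]], "imu")
  io_opt <- build_ann1_io(trials[[1]], "optical")
  expect_gt(mean(abs(io_imu$Y - io_opt$Y)), 0)
  angles <- imu2grf:::ref_angle_matrix(trials[[1]], "imu")
  y_imu <- build_ann2_io(angles, trials[[1]])$Y
  y_opt <- build_ann2_io(imu2grf:::ref_angle_matrix(trials[[1]], "optical"),
                         trials[[1]])$Y
  expect_equal(y_imu, y_opt)   # force targets identical across schemes
})

test_that("estimators round-trip through the versioned model file", {
  ds <- small_dataset()
  trials <- ds$trial[ds$subject_id == ds$subject_id[1] & ds$speed != 12]
  est <- build_estimator(trials, config = tiny_config(seed = 9, maxit = 30))
  test_trial <- ds$trial[ds$subject_id == ds$subject_id[1] & ds$speed == 12][[1]]
  before <- estimate(est, test_trial)
  path <- withr::local_tempfile(fileext = ".rds")
  save_estimator(est, path)
  back <- load_estimator(path)
  after <- estimate(back, test_trial)
  expect_identical(after, before)
  expect_identical(back$scheme, est$scheme)
  expect_identical(back$feature_set, est$feature_set)
  # truncated file: explicit error, not a garbage model
  raw <- readBin(path, "raw", n = file.size(path))
  bad_path <- withr::local_tempfile(fileext = ".rds")
  writeBin(raw[seq_len(floor(length(raw) / 2))], bad_path)
  expect_error(load_estimator(bad_path), class = "imu2grf_bad_model_file")
  # wrong version header
  other <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(version = "imu2grf-model-v0", estimator = est), other)
  expect_error(load_estimator(other), class = "imu2grf_model_version")
})
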