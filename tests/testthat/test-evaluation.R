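# Evaluation drivers at reduced scale: shapes, determinism, leakage checks,
# scheme behavior, and report round-trips.

test_that("the single-subject scenario produces the full report shape", {
  ds <- small_dataset()
  sid <- ds$subject_id[1]
  res <- cached("ss_result",
                scenario_single_subject(ds, sid, config = tiny_config(seed = 5,
                                                                      maxit = 60)))
  expect_s3_class(res, "scenario_result")
  expect_setequal(unique(res$agreement$signal), c("knee_fe", "vgrf"))
  expect_setequal(unique(res$agreement$side), c("left", "right"))
  expect_setequal(res$discrete_summary$measure,
                  c("max_knee_flexion_stance", "peak_vgrf", "t_passive_peak",
                    "loading_rate"))
  expect_true(all(res$ttests$measure != "t_passive_peak"))
  expect_true(all(res$agreement$rho_mean >= -1 & res$agreement$rho_mean <= 1))
  expect_error(scenario_single_subject(ds, "S99", config = tiny_config()),
               class = "imu2grf_missing_trial")
  # no trial exists at 11 km/h
  expect_error(scenario_single_subject(ds, sid, test_speed = 11,
                                       config = tiny_config()),
               class = "imu2grf_missing_trial")
})

test_that("scenario runs are deterministic end to end", {
  ds <- small_dataset()
  sid <- ds$subject_id[1]
  r1 <- cached("ss_result",
               scenario_single_subject(ds, sid, config = tiny_config(seed = 5,
                                                                     maxit = 60)))
  r2 <- scenario_single_subject(ds, sid, config = tiny_config(seed = 5,
                                                              maxit = 60))
  expect_equal(r1$agreement, r2$agreement, tolerance = 1e-15)
  expect_equal(r1$discrete, r2$discrete, tolerance = 1e-15)
})

test_that("training matrices contain no rows of the evaluation trial", {
  ds <- small_dataset()
  sid <- ds$subject_id[1]
  train_trials <- ds$trial[ds$subject_id == sid & ds$speed != 12]
  test_trial <- ds$trial[ds$subject_id == sid & ds$speed == 12][[1]]
  X_train <- do.call(rbind, lapply(train_trials,
                                   function(t) build_ann1_io(t)$X))
  X_test <- build_ann1_io(test_trial)$X
  expect_length(intersect(row_fingerprints(X_train),
                          row_fingerprints(X_test)), 0)
})

test_that("LOSO trains across subjects and needs at least two", {
  ds <- small_dataset()
  res <- cached("loso_result",
                scenario_loso(ds, ds$subject_id[1], config = tiny_config(seed = 6,
                                                                         maxit = 60),
                              kinetics = FALSE))
  expect_s3_class(res, "scenario_result")
  expect_equal(res$scenario, "leave_one_subject_out")
  expect_setequal(unique(res$agreement$signal), "knee_fe")
  solo <- ds[ds$subject_id == ds$subject_id[1], ]
  expect_error(scenario_loso(solo, ds$subject_id[1], config = tiny_config()),
               class = "imu2grf_missing_trial")
})

test_that("each scheme agrees best with its own reference", {
  ds <- small_dataset()
  sid <- ds$subject_id[2]
  test_trial <- ds$trial[ds$subject_id == sid & ds$speed == 12][[1]]
  rhos <- sapply(c("imu", "optical"), function(sch) {
    trials <- ds$trial[ds$subject_id == sid & ds$speed != 12]
    est <- build_estimator(trials, scheme = sch,
                           config = tiny_config(seed = 11, maxit = 60),
                           train_ann2 = FALSE)
    sapply(c("imu", "optical"), function(ref) {
      ev <- evaluate_trial(est, test_trial, scheme = ref)
      mean(ev$agreement$rho_mean[ev$agreement$signal == "knee_fe"])
    })
  })
  # rows: reference scored against; columns: training scheme
  expect_gte(rhos["imu", "imu"], rhos["optical", "imu"])
  expect_gte(rhos["optical", "optical"], rhos["imu", "optical"])
})

test_that("the feature ablation covers all five sets deterministically", {
  ds <- small_dataset()
  sid <- ds$subject_id[1]
  tab <- cached("ablation",
                feature_ablation(ds, sid, config = tiny_config(seed = 3,
                                                               maxit = 40)))
  expect_setequal(unique(tab$feature_set), names(FEATURE_SETS))
  expect_equal(nrow(tab), 10L)   # 5 sets x 2 sides
  tab2 <- feature_ablation(ds, sid, config = tiny_config(seed = 3, maxit = 40))
  expect_equal(tab, tab2, tolerance = 1e-15)
})

test_that("speed generalization reports one row set per evaluated speed", {
  ds <- small_dataset()
  sid <- ds$subject_id[1]
  sg <- cached("speedgen",
               speed_generalization(ds, sid, config = tiny_config(seed = 4,
                                                                  maxit = 40)))
  expect_setequal(unique(sg$agreement$speed), c(10, 12, 14))
  expect_setequal(unique(sg$discrete$speed), c(10, 12, 14))
  expect_true(all(c("max_knee_flexion_stance", "peak_vgrf", "loading_rate")
                  %in% sg$discrete$measure))
})

test_that("reports render and round-trip through JSON losslessly", {
  r1 <- cached("ss_result",
               scenario_single_subject(small_dataset(),
                                       small_dataset()$subject_id[1],
                                       config = tiny_config(seed = 5,
                                                            maxit = 60)))
  rep <- render_report(list(r1))
  expect_s3_class(rep, "run_report")
  txt <- capture.output(print(rep))
  expect_true(any(grepl("Continuous agreement", txt)))
  path <- withr::local_tempfile(fileext = ".json")
  report_to_json(rep, path)
  back <- report_from_json(path)
  expect_equal(as.data.frame(back$agreement), as.data.frame(rep$agreement),
               tolerance = 1e-12)
  expect_equal(as.data.frame(back$discrete), as.data.frame(rep$discrete),
               tolerance = 1e-12)
  expect_error(render_report(list()), class = "imu2grf_empty")
})

test_that("cohort summaries aggregate subject means with a paired test", {
  ds <- small_dataset()
  res <- lapply(unique(ds$subject_id), function(sid) {
    scenario_single_subject(ds, sid, config = tiny_config(seed = 5, maxit = 40))
  })
  cs <- cohort_summary(res)
  expect_equal(nrow(cs$subject_means),
               length(unique(ds$subject_id)) * 4L)
  expect_setequal(cs$cohort_tests$measure,
                  c("max_knee_flexion_stance", "peak_vgrf", "loading_rate"))
})
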