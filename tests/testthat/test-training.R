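test_that("split_train_test halves each sample-label class with a ceiling rule", {
  calls <- toy_labeled(n_tp = 100, n_fp = 10, n_samples = 1)
  halves <- split_train_test(calls, seed = 3)
  expect_equal(sum(halves$train$label == "TP"), 50)
  expect_equal(sum(halves$train$label == "FP"), 5)
  expect_equal(sum(halves$test$label == "TP"), 50)
  expect_equal(sum(halves$test$label == "FP"), 5)

  # odd class size: training side gets the ceiling
  odd <- toy_labeled(n_tp = 101, n_fp = 4, n_samples = 1)
  h2 <- split_train_test(odd, seed = 3)
  expect_equal(sum(h2$train$label == "TP"), 51)
  expect_equal(sum(h2$test$label == "TP"), 50)

  # determinism
  h3 <- split_train_test(calls, seed = 3)
  expect_identical(halves$train, h3$train)
  expect_warning(
    split_train_test(dplyr::filter(calls, label == "TP")),
    "no FP calls"
  )
})

test_that("all four learners fit, score in [0,1], and separate easy classes", {
  dat <- toy_labeled(n_tp = 150, n_fp = 60, sep = 5)
  y <- as.integer(dat$label == "FP")
  for (alg in learner_algorithms()) {
    fit <- fit_learner(alg, list(), dat[c("f1", "f2")], y, seed = 2)
    s <- predict_scores(fit, dat[c("f1", "f2")])
    expect_true(all(s >= 0 & s <= 1))
    expect_gt(roc_auc(s, y), 0.95)
  }
  expect_error(fit_learner("adaboost", list(), dat[c("f1", "f2")], rep(0L, nrow(dat))), "both classes")
})

test_that("loso_cv leaves each sample out once and summarises the winner", {
  dat <- toy_labeled(n_tp = 300, n_fp = 60, sep = 3, n_samples = 3)
  grid <- small_learner_grid()
  grid <- grid[grid$algorithm %in% c("gradientboosting", "randomforest"), ]
  cv <- loso_cv(dat, grid = grid, seed = 7)

  expect_setequal(unique(cv$fold_metrics$left_out), c("s1", "s2", "s3"))
  per_fold <- dplyr::distinct(cv$fold_metrics, grid_id, left_out)
  expect_equal(nrow(per_fold), 2 * 3) # grid points x folds
  expect_equal(nrow(cv$best), 2)
  # lower bound is exactly mean - 2 * sd
  expect_equal(
    cv$cv_summary$lower_bound,
    cv$cv_summary$mean_capture - 2 * cv$cv_summary$sd_capture
  )
  expect_equal(unique(cv$cv_summary$n_folds), 3)

  # determinism: identical seed reproduces the summary exactly
  cv2 <- loso_cv(dat, grid = grid, seed = 7)
  expect_identical(cv$cv_summary, cv2$cv_summary)
  expect_identical(tidy(cv), cv$cv_summary)
})

test_that("train_final calibrates thresholds and meets targets on well-separated data", {
  dat <- toy_labeled(n_tp = 400, n_fp = 80, sep = 8, n_samples = 2)
  halves <- split_train_test(dat, seed = 5)
  model <- train_final(halves$train, halves$test, "gradientboosting",
    list(nrounds = 30L),
    seed = 5, stratum = "snv-het", schema_id = "toy"
  )
  expect_s3_class(model, "calibrated_model")
  expect_true(all(diff(model$thresholds$threshold) <= 0))
  # disjoint feature supports: perfect capture, no needless flags
  expect_true(all(model$final_metrics$capture_rate == 1))
  expect_true(all(model$final_metrics$tp_flag_rate <= 0.01))

  # on the calibration data itself the guarantee is exact at every target
  tr_scores <- predict(model, halves$train)
  tr_fp <- tr_scores[halves$train$label == "FP"]
  achieved <- vapply(model$thresholds$threshold,
    function(t) mean(tr_fp >= t),
    numeric(1)
  )
  expect_true(all(achieved >= model$thresholds$target))

  flags <- predict(model, halves$test, target = 1.0, type = "flag")
  expect_type(flags, "logical")
  expect_error(predict(model, halves$test, target = 0.1234, type = "flag"), "calibrated")
})

test_that("predictions refuse calls extracted under a different schema", {
  dat <- toy_labeled(n_tp = 60, n_fp = 20, sep = 4)
  halves <- split_train_test(dat, seed = 1)
  model <- train_final(halves$train, halves$test, "randomforest", list(),
    seed = 1, schema_id = "dragen-like"
  )
  other <- halves$test
  attr(other, "schema_id") <- "strelka2-like"
  expect_error(predict(model, other), "Schema mismatch")
})

test_that("with no signal the TP flag rate converges to the target capture rate", {
  # Labels independent of features: scores of fresh TP and FP calls are
  # exchangeable, so a threshold calibrated out-of-sample at capture c
  # flags close to a fraction c of true positive calls. Calibration uses a
  # held-out sample (in-sample calibration would be biased by overfit).
  cfg <- synthetic_config(
    n_samples = 3, calls_per_sample = 20000,
    stratum_mix = c("snv-het" = 1),
    fp_prevalence = c("snv-het" = 0.5),
    separation = 0, seed = 202
  )
  s1 <- simulate_sample_calls(cfg, "a", seed = 101)
  s2 <- simulate_sample_calls(cfg, "b", seed = 102)
  s3 <- simulate_sample_calls(cfg, "c", seed = 103)
  feats <- c("qual", "gq", "dp", "mq", "qd", "af")
  fit <- fit_learner(
    "gradientboosting", list(nrounds = 40L),
    s1[feats], as.integer(s1$label == "FP"),
    seed = 11
  )
  cal_fp <- predict_scores(fit, s2[s2$label == "FP", feats])
  eval_tp <- predict_scores(fit, s3[s3$label == "TP", feats])
  for (target in c(0.99, 0.995)) {
    thr <- calibrate_threshold(cal_fp, target)
    tp_flag <- mean(eval_tp >= thr)
    tol <- 3 * sqrt(target * (1 - target) * (1 / length(cal_fp) + 1 / length(eval_tp)))
    expect_lt(abs(tp_flag - target), tol + 0.001)
  }
})
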