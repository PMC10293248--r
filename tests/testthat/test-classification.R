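test_that("task datasets have the expected rows and columns", {
  withr::local_seed(31)
  fx <- synthetic_feature_table()  # 27 CG / 24 PD / 26 DD
  expect_equal(nrow(make_task_dataset(fx, "Task1")$x), 51)
  expect_equal(nrow(make_task_dataset(fx, "Task2")$x), 77)
  expect_equal(nrow(make_task_dataset(fx, "Task3")$x), 50)
  expect_equal(ncol(make_task_dataset(fx, "Task1", "questionnaire_only")$x), 1)
  expect_equal(ncol(make_task_dataset(fx, "Task1", "tablet_only")$x), 13)
  expect_equal(ncol(make_task_dataset(fx, "Task1", "integrated")$x), 14)
  ds2 <- make_task_dataset(fx, "Task2")
  expect_equal(sum(ds2$y), 50)  # PD + DD are the positive class
})

test_that("majority baseline reproduces the class-proportion accuracies", {
  expect_equal(round(majority_baseline(rep(c(0, 1), c(27, 24))), 2), 0.53)
  expect_equal(round(majority_baseline(rep(c(0, 1), c(27, 50))), 2), 0.65)
  expect_equal(round(majority_baseline(rep(c(0, 1), c(26, 24))), 2), 0.52)
  expect_warning(one <- majority_baseline(rep(1, 10)), "single-class")
  expect_equal(one, 1)
})

test_that("cross-validation is stratified, deterministic and leak-free", {
  withr::local_seed(32)
  fx <- synthetic_feature_table(signal_strength = 4)
  ds <- make_task_dataset(fx, "Task1")
  cfg <- model_config(seed = 99, nrounds = 30)
  cv1 <- run_cv(ds, cfg, keep_models = FALSE)

  # every participant predicted exactly once
  expect_setequal(cv1$oof$participant_id, ds$ids)
  expect_equal(nrow(cv1$oof), length(ds$y))

  # stratification: fold class counts within 1 of proportionality
  for (f in cv1$folds) {
    frac <- mean(ds$y[f])
    expect_lte(abs(sum(ds$y[f]) - mean(ds$y) * length(f)), 1)
    expect_true(frac > 0 && frac < 1)
  }

  # determinism
  cv2 <- run_cv(ds, cfg, keep_models = FALSE)
  expect_equal(cv1$oof, cv2$oof)
  expect_equal(cv1$fold_metrics, cv2$fold_metrics)

  # a deliberately leaky variant must change predictions
  cv_leak <- run_cv(ds, cfg, keep_models = FALSE,
                    leaky_preprocessing = TRUE)
  expect_false(identical(cv1$oof$prob, cv_leak$oof$prob))
})

test_that("a perfectly separating feature yields perfect accuracy", {
  withr::local_seed(34)
  fx <- synthetic_feature_table(signal_strength = 0)
  fx$QYes <- ifelse(fx$group == "CG", 1, 25) + round(rnorm(nrow(fx)))
  cv <- run_cv(make_task_dataset(fx, "Task1", "questionnaire_only"),
               model_config(seed = 3, nrounds = 30), keep_models = FALSE)
  expect_equal(cv$means[["accuracy"]], 1)
})

test_that("labels shuffled independently of features score near the baseline", {
  withr::local_seed(35)
  fx <- synthetic_feature_table(signal_strength = 0)
  for (f in feature_names()) fx[[f]] <- rnorm(nrow(fx))
  ds <- make_task_dataset(fx, "Task1")
  cv <- run_cv(ds, model_config(seed = 7, nrounds = 30),
               keep_models = FALSE)
  base <- majority_baseline(ds$y, seed = 7)
  expect_lt(abs(cv$means[["accuracy"]] - base), 0.15)
})

test_that("error on classes smaller than the fold count is informative", {
  withr::local_seed(36)
  fx <- synthetic_feature_table(n_cg = 4, n_pd = 4, n_dd = 4)
  expect_error(run_cv(make_task_dataset(fx, "Task1"), model_config()),
               "fewer")
})

test_that("TreeSHAP contributions are additive and match the library cross-check", {
  withr::local_seed(37)
  x <- matrix(rnorm(80 * 6), 80, 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  y <- as.integer(x[, 1] + 0.5 * x[, 2] + rnorm(80, 0, 0.5) > 0)
  bst <- spiraldx:::fit_xgb(x, y, model_config(seed = 5, nrounds = 60))
  sv <- treeshap_values(bst, x)

  # additivity to the raw model output, double precision
  expect_lt(max(abs(rowSums(sv$phi) - sv$margin)), 1e-6)

  # the double-precision margin agrees with the library's prediction
  marg32 <- predict(bst, xgboost::xgb.DMatrix(x, nthread = 1),
                    outputmargin = TRUE)
  expect_lt(max(abs(sv$margin - marg32)), 1e-4)

  # independent cross-check: the library's own float32 TreeSHAP
  contrib <- predict(bst, xgboost::xgb.DMatrix(x, nthread = 1),
                     predcontrib = TRUE)
  expect_lt(max(abs(sv$phi - contrib)), 1e-4)
})

test_that("a pure-noise feature ranks last in SHAP importance", {
  withr::local_seed(38)
  fx <- synthetic_feature_table(signal_strength = 3)
  # make every motor feature informative except one pure-noise column
  diseased <- as.integer(fx$group != "CG")
  for (f in setdiff(feature_names(), "QYes")) {
    fx[[f]] <- rnorm(nrow(fx), 2 * diseased, 1)
  }
  fx$F7_ChangesOfDirectionY <- rnorm(nrow(fx))  # no signal
  cv <- run_cv(make_task_dataset(fx, "Task2"),
               model_config(seed = 11, nrounds = 50))
  rank_tbl <- shap_ranking(shap_importance(cv))
  expect_identical(rank_tbl$feature[nrow(rank_tbl)],
                   "F7_ChangesOfDirectionY")
})

test_that("a dominant questionnaire signal puts QYes first for Task 1", {
  withr::local_seed(39)
  fx <- synthetic_feature_table(signal_strength = 0)
  fx$QYes <- ifelse(fx$group == "CG", 2, 12) +
    pmax(-2, pmin(2, round(rnorm(nrow(fx)))))
  for (f in setdiff(feature_names(), "QYes")) {
    fx[[f]] <- rnorm(nrow(fx), 0.2 * (fx$group == "PD"), 1)
  }
  cv <- run_cv(make_task_dataset(fx, "Task1"),
               model_config(seed = 13, nrounds = 50))
  rank_tbl <- shap_ranking(shap_importance(cv))
  expect_identical(rank_tbl$feature[1L], "QYes")
})

test_that("error analysis recounts the misclassified subgroups", {
  meta <- tibble::tibble(
    participant_id = sprintf("P%d", 1:6),
    group = c("CG", "CG", "PD", "PD", "PD", "PD"),
    age = c(50, 60, 70, 75, 80, 65),
    gender = c("female", "male", "female", "female", "male", "male"),
    hoehn_yahr = c(NA, NA, 2, 2, 3, 1), QYes = c(3, 4, 10, 12, 8, 9))
  oof <- tibble::tibble(
    participant_id = meta$participant_id, fold = 1,
    truth = c(0, 0, 1, 1, 1, 1), prob = 0.5,
    pred = c(1, 1, 0, 1, 1, 1))  # two FPs (ages 50, 60), one FN (age 70)
  cv <- structure(list(task = "Task1", oof = oof), class = "cv_result")
  ea <- error_analysis(cv, meta)
  fp <- ea[ea$error_class == "FP", ]
  expect_equal(fp$n, 2)
  expect_equal(fp$mean_age, 55)
  expect_equal(fp$n_female, 1L)
  fn <- ea[ea$error_class == "FN", ]
  expect_equal(fn$n, 1)
  expect_equal(fn$mean_qyes, 10)
  expect_equal(fn$mean_hy, 2)

  # perfect classifier: zero counts, blank statistics
  oof$pred <- oof$truth
  cv2 <- structure(list(task = "Task1", oof = oof), class = "cv_result")
  ea2 <- error_analysis(cv2, meta)
  expect_equal(ea2$n, c(0, 0))
  expect_true(all(is.na(ea2$mean_age)))
})

test_that("error subgroup means match a direct recount oracle", {
  withr::local_seed(40)
  fx <- synthetic_feature_table(n_cg = 12, n_pd = 12, n_dd = 12)
  cv <- run_cv(make_task_dataset(fx, "Task2"),
               model_config(seed = 17, nrounds = 30), keep_models = FALSE)
  meta <- fx[, c("participant_id", "group", "age", "gender", "hoehn_yahr",
                 "QYes")]
  ea <- error_analysis(cv, meta)
  m <- merge(as.data.frame(cv$oof), as.data.frame(meta),
             by = "participant_id")
  fp_ids <- m$participant_id[m$truth == 0 & m$pred == 1]
  expect_equal(ea$n[ea$error_class == "FP"], length(fp_ids))
  if (length(fp_ids) > 0) {
    expect_equal(ea$mean_age[ea$error_class == "FP"],
                 mean(meta$age[meta$participant_id %in% fp_ids]))
  }
  expect_setequal(ea$error_class, c("FP", "FN_PD", "FN_DD"))
})
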