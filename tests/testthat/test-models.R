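test_that("AUC rank statistic equals the pair-counting oracle", {
  # the worked 6-row example: 9 positive-negative pairs, 8 concordant
  labels <- c(1, 1, 1, 0, 0, 0)
  scores <- c(0.9, 0.8, 0.4, 0.7, 0.3, 0.2)
  expect_equal(auc_score(scores, labels), 8 / 9)
  expect_equal(auc_pairs(scores, labels), 8 / 9)
  # randomized toys up to 50 rows, with heavy ties
  withr::with_seed(42, {
    for (rep in 1:25) {
      n <- sample(4:50, 1)
      y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
      s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
      expect_equal(auc_score(s, y), auc_pairs(s, y))
    }
  })
  # conventions: oracle scores, anti-predictor, constant scores
  y <- rep(c(1, 0), 10)
  expect_equal(auc_score(y, y), 1)
  expect_equal(auc_score(1 - y, y), 0)
  expect_equal(auc_score(rep(0.3, 20), y), 0.5)
})

test_that("ridge logistic matches a directly optimized penalized likelihood", {
  withr::with_seed(5, {
    n <- 20
    x <- cbind(a = rnorm(n), b = rnorm(n))
    y <- as.integer(x[, 1] + 0.5 * x[, 2] + rnorm(n) > 0)
  })
  fm <- feature_matrix(x, y)
  model <- train_model(model_spec("logistic"), fm)
  gl <- c(as.numeric(model$fit$a0), as.numeric(stats::coef(model$fit))[-1])
  C <- 6
  obj <- function(b) {
    eta <- b[1] + x %*% b[2:3]
    mean(log(1 + exp(eta)) - y * eta) + sum(b[2:3]^2) / (2 * n * C)
  }
  op <- stats::optim(c(0, 0, 0), obj, method = "BFGS",
                     control = list(reltol = 1e-14, maxit = 1000))
  expect_lt(max(abs(gl - op$par)), 1e-4)
})

test_that("every family emits probabilities and separates an easy toy", {
  fm <- make_toy_fm(n0 = 120, n1 = 40, p = 3, sep = 4, seed = 20)
  small_hp <- list(
    logistic = list(),
    neural_net = list(hidden_units = 16L, max_iter = 30L),
    xgboost = list(max_depth = 3L, nrounds = 50L),
    random_forest = list(num_trees = 50L),
    balanced_random_forest = list(num_trees = 50L),
    balanced_bagging = list(num_trees = 50L)
  )
  for (fam in names(small_hp)) {
    model <- train_model(model_spec(fam, small_hp[[fam]], seed = 3), fm)
    risk <- predict_risk(model, fm)
    expect_true(all(risk >= 0 & risk <= 1), label = paste(fam, "range"))
    expect_gt(auc_score(risk, fm$y), 0.95)
  }
})

test_that("training refuses degenerate labels and mismatched columns error", {
  fm <- make_toy_fm(n0 = 30, n1 = 10, seed = 1)
  allneg <- feature_matrix(fm$x, rep(0L, 40))
  expect_error(train_model(model_spec("logistic"), allneg), "degenerate")
  model <- train_model(model_spec("logistic"), fm)
  bad <- fm
  colnames(bad$x) <- c("f1", "f2", "zzz")
  expect_error(predict_risk(model, bad), "zzz")
})

test_that("logistic separates a linearly separable toy perfectly", {
  x <- cbind(u = c(rep(0, 10), rep(3, 10)), v = rep(0, 20))
  y <- rep(0:1, each = 10)
  model <- train_model(model_spec("logistic"), feature_matrix(x, y))
  risk <- predict_risk(model, feature_matrix(x, y))
  expect_equal(as.integer(risk >= 0.5), y)
})

test_that("the hinge-margin link preserves ranking and hence AUC", {
  fm <- make_toy_fm(n0 = 150, n1 = 50, p = 3, sep = 1.5, seed = 30)
  model <- train_model(model_spec("xgboost", list(max_depth = 3L, nrounds = 60L),
                                  seed = 2), fm)
  margin <- stats::predict(model$fit, xgboost::xgb.DMatrix(fm$x),
                           outputmargin = TRUE)
  risk <- predict_risk(model, fm)
  expect_equal(order(risk), order(margin))
  expect_equal(auc_score(risk, fm$y), auc_score(margin, fm$y))
})

test_that("cross-validation pools exactly the training rows and is deterministic", {
  fm <- make_toy_fm(n0 = 80, n1 = 24, p = 3, sep = 2, seed = 40)
  spec <- model_spec("logistic", balance = balance_spec(0.5, 0.8, seed = 1))
  r1 <- cross_validate(spec, fm, k = 4, seed = 9, n_boot = 50)
  r2 <- cross_validate(spec, fm, k = 4, seed = 9, n_boot = 50)
  expect_equal(r1$auc$estimate, r2$auc$estimate)
  expect_equal(r1$n_eval, fm_nrow(fm))   # no synthetic rows leak into evaluation
  expect_error(cross_validate(spec, fm, k = 30, seed = 1), "smaller k")
})

test_that("evaluation report: point metrics, CI ordering, calibration mass balance", {
  fm <- make_toy_fm(n0 = 160, n1 = 40, p = 3, sep = 2, seed = 50)
  model <- train_model(model_spec("random_forest", list(num_trees = 60L),
                                  seed = 1), fm)
  rep <- evaluate_on_test(model, fm, n_boot = 200, seed = 3)
  for (m in list(rep$auc, rep$sensitivity, rep$specificity)) {
    expect_lte(m$ci_lower, m$estimate)
    expect_lte(m$estimate, m$ci_upper)
  }
  cal <- rep$calibration
  expect_equal(sum(cal$n), rep$n_eval)
  expect_equal(sum(cal$n * cal$obs_rate) / sum(cal$n), mean(fm$y),
               tolerance = 1e-9)
  # perfect separation toy
  x <- cbind(a = c(rep(0, 20), rep(5, 8)), b = 0)
  yy <- c(rep(0L, 20), rep(1L, 8))
  m2 <- train_model(model_spec("logistic"), feature_matrix(x, yy))
  r2 <- evaluate_on_test(m2, feature_matrix(x, yy), n_boot = 100, seed = 1)
  expect_equal(r2$auc$estimate, 1)
  expect_equal(r2$sensitivity$estimate, 1)
  expect_equal(r2$specificity$estimate, 1)
})

test_that("calibration bins are equal-count deciles with hand-checked means", {
  risk <- seq(0.05, 1, by = 0.05)
  y <- c(0, 0, 1, 0, 0, 0, 0, 1, 0, 0, 0, 1, 1, 0, 1, 1, 1, 0, 1, 1)
  cal <- calibration_curve(risk, y, n_bins = 2)
  expect_equal(cal$n, c(10, 10))
  expect_equal(cal$mean_pred, c(mean(risk[1:10]), mean(risk[11:20])))
  expect_equal(cal$obs_rate, c(0.2, 0.7))
  # risk identical to labels: extreme bins are pure
  cal2 <- calibration_curve(as.numeric(y), y, n_bins = 10)
  expect_equal(cal2$obs_rate[1], 0)
  expect_equal(cal2$obs_rate[10], 1)
  # constant risk at the prevalence: every bin near the prevalence
  cal3 <- calibration_curve(rep(0.3, 200), rep(c(0, 0, 0, 0, 0, 0, 0, 1, 1, 1), 20),
                            n_bins = 10)
  expect_equal(cal3$mean_pred, rep(0.3, 10))
  expect_equal(mean(cal3$obs_rate), 0.3, tolerance = 0.1)
  expect_error(calibration_curve(risk[1:5], y[1:5], n_bins = 10), "at least")
})

test_that("bootstrap 95% CI covers a known AUC in most replicates", {
  # two binormal classes: true AUC = pnorm(delta / sqrt(2))
  delta <- 1.2
  true_auc <- pnorm(delta / sqrt(2))
  hits <- withr::with_seed(77, {
    vapply(1:200, function(r) {
      s <- c(rnorm(150), rnorm(40, delta))
      y <- c(rep(0, 150), rep(1, 40))
      rep <- eval_report(plogis(s), y, n_boot = 400, seed = r)
      rep$auc$ci_lower <= true_auc && true_auc <= rep$auc$ci_upper
    }, logical(1))
  })
  expect_gte(mean(hits), 0.90)
})

test_that("feature importance recovers planted signal and flags its method", {
  cfg <- cohort_config(n_cases = 3000, seed = 61,
                       effect_sizes = c(female_sex = 0, log_duration = 0.4,
                                        bmi = 0, age = 0))
  co <- generate_cohort(cfg)
  fm <- encode_features(co$cases)
  model <- train_model(model_spec("xgboost", list(max_depth = 3L, nrounds = 150L),
                                  seed = 1), fm)
  imp <- feature_importance(model, fm)
  expect_equal(unique(imp$method), "shap")
  expect_equal(imp$feature[1], "scheduled_duration")
  # a pure-noise feature lands in the bottom half for permutation importance too
  rf <- train_model(model_spec("random_forest", list(num_trees = 100L), seed = 1),
                    fm)
  imp_rf <- feature_importance(rf, fm, method = "permutation", n_repeats = 2)
  expect_equal(unique(imp_rf$method), "permutation")
  expect_equal(imp_rf$feature[1], "scheduled_duration")
  # a label-independent noise flag sits at the noise floor, far below the signal
  noise_imp <- imp_rf$importance[imp_rf$feature == "anxiety"]
  expect_lt(abs(noise_imp), 0.05 * imp_rf$importance[1])
})

test_that("default synthetic effects put duration, BMI and age in the top ranks", {
  cfg <- cohort_config(n_cases = 6000, seed = 71)
  co <- generate_cohort(cfg)
  fm <- encode_features(co$cases)
  # attribution on an unbalanced fit: resampling distorts one-hot marginals
  # and induces spurious attributions on frequent categorical levels
  model <- train_model(model_spec("xgboost", list(max_depth = 3L, nrounds = 200L),
                                  seed = 1), fm)
  imp <- feature_importance(model, fm)
  expect_true(all(c("scheduled_duration", "bmi", "age") %in% imp$feature[1:5]))
})
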