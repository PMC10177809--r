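test_that("metrics match hand evaluation of the confusion-table formulas", {
  # TP=3, TN=2, FP=1, FN=1 worked by direct substitution
  y_true <- c(1, 1, 1, 1, 0, 0, 0)
  y_score <- c(0.9, 0.8, 0.7, 0.2, 0.6, 0.3, 0.1)
  m <- compute_metrics(y_true, y_score)
  expect_equal(unname(m["ACC"]), 5 / 7)
  expect_equal(unname(m["Sn"]), 3 / 4)
  expect_equal(unname(m["Sp"]), 2 / 3)
  expect_equal(unname(m["F1"]), 6 / 8)
  expect_equal(unname(m["MCC"]), (3 * 2 - 1 * 1) / sqrt(4 * 4 * 3 * 3))
})

test_that("perfect and degenerate scores hit the metric boundaries", {
  y <- c(1, 1, 0, 0)
  m <- compute_metrics(y, c(0.9, 0.8, 0.2, 0.1))
  expect_equal(unname(m[c("ACC", "AUC", "Sn", "Sp", "F1", "MCC")]),
               c(1, 1, 1, 1, 1, 1))
  expect_error(compute_metrics(c(1, 1), c(0.2, 0.3)), "single class")
  # all predicted positive: MCC denominator vanishes, reported as 0
  m0 <- compute_metrics(y, c(0.9, 0.9, 0.9, 0.9), threshold = 0.5)
  expect_equal(unname(m0["MCC"]), 0)
})

test_that("confusion-table identities hold over all small tables", {
  for (P in 1:6) for (N in 1:6) for (TP in 0:P) for (TN in 0:N) {
    cc <- c(TP = TP, TN = TN, FP = N - TN, FN = P - TP)
    m <- metrics_from_counts(cc)
    expect_equal(unname(m["ACC"]),
                 (m[["Sn"]] * P + m[["Sp"]] * N) / (P + N))
    expect_equal(unname(m["F1"]), 2 * TP / (2 * TP + (N - TN) + (P - TP)))
    den <- (TP + N - TN) * P * N * (TN + P - TP)
    expected_mcc <- if (den > 0) (TP * TN - (N - TN) * (P - TP)) / sqrt(den) else 0
    expect_equal(unname(m["MCC"]), expected_mcc)
  }
})

test_that("rank-based AUC is near 0.5 for random scores and matches pROC", {
  set.seed(61)
  y <- rep(c(0, 1), 500)
  s <- runif(1000)
  expect_equal(auc_score(y, s), 0.5, tolerance = 0.06)
  # independent implementation cross-check, including with ties
  s_tied <- round(s, 1)
  expect_equal(auc_score(y, s_tied),
               as.numeric(pROC::auc(pROC::roc(y, s_tied, quiet = TRUE,
                                              direction = "<"))))
  # invariance under strictly monotone score transforms
  expect_equal(auc_score(y, s), auc_score(y, qlogis(s)))
})

test_that("ROC endpoints, trapezoid area and PR conventions are consistent", {
  set.seed(62)
  y <- rep(c(0, 1), 50)
  s <- runif(100) + 0.3 * y
  cu <- curves(y, s)
  expect_equal(cu$roc$fpr[1], 0)
  expect_equal(cu$roc$tpr[1], 0)
  expect_equal(cu$roc$fpr[nrow(cu$roc)], 1)
  expect_equal(cu$roc$tpr[nrow(cu$roc)], 1)
  trap <- sum(diff(cu$roc$fpr) *
                (utils::head(cu$roc$tpr, -1) + utils::tail(cu$roc$tpr, -1)) / 2)
  expect_equal(trap, auc_score(y, s), tolerance = 1e-9)
  expect_equal(cu$pr$precision[1], 1)   # precision 1 at recall 0
  # perfect classifier passes through (0, 1)
  cu_perf <- curves(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))
  expect_true(any(cu_perf$roc$fpr == 0 & cu_perf$roc$tpr == 1))
})

test_that("stratified folds are disjoint, covering, class-balanced and seeded", {
  y <- rep(c(0L, 1L), c(70, 30))
  f1 <- make_folds(y, k = 10, seed = 3)
  f2 <- make_folds(y, k = 10, seed = 3)
  expect_identical(f1, f2)
  expect_equal(sort(unique(f1)), 1:10)
  expect_equal(tabulate(f1), rep(10L, 10))                 # covering partition
  for (f in 1:10) expect_equal(sum(y[f1 == f]), 3L)        # stratification
  f3 <- make_folds(y, k = 10, seed = 4)
  expect_false(identical(f1, f3))
  expect_error(make_folds(rep(c(0L, 1L), c(98, 2)), k = 10), "single class")
})

test_that("cross-validation validates each sample once and reproduces under the seed", {
  set.seed(63)
  d <- planted_features(n = 100, n_signal = 2, n_noise = 4)
  cfg <- model_config(iterations = 30, depth = 3, learning_rate = 0.3)
  r1 <- cross_validate(d$X, d$y, k = 5, seed = 8, config = cfg)
  r2 <- cross_validate(d$X, d$y, k = 5, seed = 8, config = cfg)
  expect_identical(r1$folds, r2$folds)
  expect_equal(tabulate(r1$fold_assignment), rep(20L, 5))
  expect_equal(unname(r1$mean), unname(colMeans(r1$folds)))
  expect_true(all(r1$sd >= 0))
  expect_gt(r1$mean[["AUC"]], 0.9)   # strong planted signal
})

test_that("the independent test guards against train/test id leakage", {
  set.seed(64)
  d <- planted_features(n = 120, n_signal = 2, n_noise = 4)
  train_idx <- 1:80
  b <- train_model(d$X[train_idx, ], d$y[train_idx],
                   model_config(iterations = 30, depth = 3, learning_rate = 0.3))
  m <- independent_test(b, d$X[-train_idx, ], d$y[-train_idx])
  expect_s3_class(m, "metric_set")
  expect_gt(m[["AUC"]], 0.9)
  expect_error(independent_test(b, d$X, d$y), "overlap")
})
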