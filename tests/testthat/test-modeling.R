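fast_cfg <- function(...) {
  model_config(iterations = 40, depth = 3, learning_rate = 0.3, ...)
}

test_that("training separates separable toy data and is seed-reproducible", {
  set.seed(51)
  d <- planted_features(n = 120, n_signal = 2, n_noise = 3, noise_sd = 0.01)
  b1 <- train_model(d$X, d$y, fast_cfg(seed = 9))
  expect_equal(predict(b1, d$X, type = "class"), d$y, ignore_attr = TRUE)
  b2 <- train_model(d$X, d$y, fast_cfg(seed = 9))
  expect_identical(predict(b1, d$X), predict(b2, d$X))
  p <- predict(b1, d$X)
  expect_true(all(p >= 0 & p <= 1))
  expect_error(train_model(d$X, rep(0L, 120), fast_cfg()), "both classes")
})

test_that("prediction refuses mismatched or silently reordered columns", {
  set.seed(52)
  d <- planted_features(n = 80, n_signal = 2, n_noise = 4)
  b <- train_model(d$X, d$y, fast_cfg())
  expect_error(predict(b, d$X[, rev(colnames(d$X))]), "reordered")
  X2 <- d$X; colnames(X2)[1] <- "renamed"
  expect_error(predict(b, X2), "renamed")
})

test_that("the MultiClass compatibility objective matches Logloss in ranking behavior", {
  set.seed(53)
  d <- planted_features(n = 120, n_signal = 2, n_noise = 4)
  b_bin <- train_model(d$X, d$y, fast_cfg(seed = 3))
  b_mc <- train_model(d$X, d$y, fast_cfg(seed = 3, loss_function = "MultiClass"))
  p_mc <- predict(b_mc, d$X)
  expect_true(all(p_mc >= 0 & p_mc <= 1))
  expect_equal(auc_score(d$y, predict(b_bin, d$X)), auc_score(d$y, p_mc),
               tolerance = 0.02)
})

test_that("persistence round-trips to identical predictions", {
  set.seed(54)
  d <- planted_features(n = 100, n_signal = 2, n_noise = 4)
  b <- train_model(d$X, d$y, fast_cfg())
  path <- withr::local_tempfile(fileext = ".ubj")
  save_model(b, path)
  b2 <- load_model(path)
  expect_identical(predict(b, d$X), predict(b2, d$X))
  expect_identical(b2$feature_names, b$feature_names)
  expect_identical(b2$train_ids, b$train_ids)
})

test_that("the default tuning grid enumerates 360 ordered candidates", {
  g <- grid_candidates(grid_spec())
  expect_equal(nrow(g), 6 * 10 * 6)
  expect_true(!is.unsorted(g$iterations))
  expect_equal(nrow(unique(g)), nrow(g))
  # single-cell grid returns that cell
  g1 <- grid_spec(iterations = 25, depth = 2, learning_rate = 0.1)
  expect_equal(nrow(grid_candidates(g1)), 1)
})

test_that("grid search picks the argmax of cross-validated AUC on a reduced grid", {
  set.seed(55)
  d <- planted_features(n = 150, n_signal = 3, n_noise = 5)
  grid <- grid_spec(iterations = c(5, 40), depth = c(1, 3),
                    learning_rate = 0.3)
  best <- grid_search(d$X, d$y, grid, cv_folds = 3, seed = 2)
  res <- attr(best, "results")
  expect_equal(nrow(res), 4)
  expect_true(all(is.finite(res$mean_auc)))
  top <- which.max(res$mean_auc)
  expect_equal(best$iterations, res$iterations[top])
  expect_equal(best$depth, res$depth[top])
  # the tuned config cannot lose to any evaluated cell
  expect_true(max(res$mean_auc) >= res$mean_auc[1])
})

test_that("null labels give chance-level CV AUC on permuted data", {
  set.seed(56)
  d <- planted_features(n = 400, n_signal = 2, n_noise = 8)
  y_perm <- sample(d$y)
  rep <- cross_validate(d$X, y_perm, k = 5, seed = 1, config = fast_cfg())
  # binomial-scale interval around 0.5 for folds of 80
  expect_gt(rep$mean[["AUC"]], 0.38)
  expect_lt(rep$mean[["AUC"]], 0.62)
})

test_that("CV AUC does not decrease with planted effect size", {
  set.seed(57)
  aucs <- vapply(c(0.05, 0.4, 2), function(effect) {
    n <- 200
    y <- rep(c(0L, 1L), length.out = n)
    X <- cbind(sig = y * effect + rnorm(n), matrix(rnorm(n * 5), ncol = 5))
    colnames(X) <- c("sig", paste0("n", 1:5))
    rownames(X) <- paste0("s", 1:n)
    cross_validate(X, y, k = 5, seed = 3, config = fast_cfg())$mean[["AUC"]]
  }, numeric(1))
  expect_true(all(diff(aucs) > -0.05))
  expect_gt(aucs[3], aucs[1])
})
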