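# Gradient-boosted decision-tree classifier: configuration, training,
# grid-search tuning, prediction and persistence.
#
# Boosting itself is delegated to xgboost; this module owns the experiment
# contracts around it (reproducibility, strict feature-name matching,
# tie-broken grid search, persistence with a JSON sidecar).

#' Boosted-tree model configuration
#'
#' The defaults are the tuned operating point of the predictor: 2000
#' boosting iterations, tree depth 9, learning rate 0.03, Newton leaf
#' estimation. `loss_function = "Logloss"` fits the binary objective
#' directly; the compatibility value `"MultiClass"` fits a two-class
#' softmax instead (equivalent in effect for 0/1 labels).
#'
#' @param iterations number of boosting rounds (>= 1).
#' @param depth tree depth, 1..16.
#' @param learning_rate shrinkage, > 0.
#' @param loss_function `"Logloss"` (default) or `"MultiClass"`.
#' @param leaf_estimation_method recorded in metadata; boosting uses
#'   second-order (Newton) leaf estimates.
#' @param seed integer seed controlling all training randomness.
#' @param nthread training threads; 1 keeps training bit-reproducible.
#' @return a list of class `model_config`.
#' @export
model_config <- function(iterations = 2000L, depth = 9L, learning_rate = 0.03,
                         loss_function = c("Logloss", "MultiClass"),
                         leaf_estimation_method = "Newton",
                         seed = 1L, nthread = 1L) {
  iterations <- as.integer(iterations)
  depth <- as.integer(depth)
  stopifnot(iterations >= 1L, depth >= 1L, depth <= 16L, learning_rate > 0)
  loss_function <- match.arg(loss_function)
  structure(list(iterations = iterations, depth = depth,
                 learning_rate = learning_rate,
                 loss_function = loss_function,
                 leaf_estimation_method = leaf_estimation_method,
                 seed = as.integer(seed), nthread = as.integer(nthread)),
            class = "model_config")
}

.xgb_params <- function(cfg) {
  base <- list(max_depth = cfg$depth, eta = cfg$learning_rate,
               nthread = cfg$nthread, seed = cfg$seed,
               tree_method = "hist")
  if (cfg$loss_function == "MultiClass") {
    c(base, list(objective = "multi:softprob", num_class = 2L,
                 eval_metric = "mlogloss"))
  } else {
    c(base, list(objective = "binary:logistic", eval_metric = "logloss"))
  }
}

#' Train the boosted-tree classifier
#'
#' @param X numeric feature matrix with unique column names and row names
#'   (window ids); no missing values.
#' @param y binary labels (0/1) aligned with the rows of `X`.
#' @param config a [model_config()].
#' @return a model bundle of class `m6am_model`: the fitted booster, the
#'   ordered feature names it expects, the ids of the training windows, and
#'   the configuration. Training is deterministic: the same inputs and seed
#'   reproduce identical predictions.
#' @export
train_model <- function(X, y, config = model_config()) {
  stopifnot(is.matrix(X), !is.null(colnames(X)))
  if (anyNA(X)) stop("X contains missing values", call. = FALSE)
  y <- as.integer(y)
  stopifnot(length(y) == nrow(X))
  if (length(unique(y)) < 2L) {
    stop("y must contain both classes", call. = FALSE)
  }
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = config$nthread)
  booster <- xgboost::xgb.train(params = .xgb_params(config), data = dtrain,
                                nrounds = config$iterations, verbose = 0)
  structure(list(booster = booster,
                 feature_names = colnames(X),
                 train_ids = rownames(X),
                 config = config),
            class = "m6am_model")
}

#' Predict m6Am probabilities and labels
#'
#' The columns of `newdata` must match the bundle's `feature_names` exactly,
#' in name and order; mismatches (including silently reordered columns) are
#' an error naming the offending features.
#'
#' @param object an `m6am_model`.
#' @param newdata numeric feature matrix.
#' @param type `"prob"` for the class-1 probability, `"class"` for the hard
#'   0/1 label at `threshold`, or `"both"` for a data frame with both.
#' @param threshold probability cutoff for hard labels.
#' @param ... unused.
#' @return numeric vector or data frame, named/rownamed by window id.
#' @export
predict.m6am_model <- function(object, newdata,
                               type = c("prob", "class", "both"),
                               threshold = 0.5, ...) {
  type <- match.arg(type)
  stopifnot(is.matrix(newdata))
  if (!identical(colnames(newdata), object$feature_names)) {
    off <- union(setdiff(colnames(newdata), object$feature_names),
                 setdiff(object$feature_names, colnames(newdata)))
    msg <- if (length(off)) {
      sprintf("mismatched feature(s): %s",
              paste(utils::head(off, 5L), collapse = ", "))
    } else {
      "feature columns are reordered relative to the trained model"
    }
    stop(sprintf("newdata does not match the model's feature contract: %s", msg),
         call. = FALSE)
  }
  dm <- xgboost::xgb.DMatrix(newdata, nthread = object$config$nthread)
  p <- predict(object$booster, dm)
  if (object$config$loss_function == "MultiClass") {
    # softmax output: one probability per class, keep class 1
    if (!is.matrix(p)) p <- matrix(p, ncol = 2L, byrow = TRUE)
    p <- p[, 2L]
  }
  names(p) <- rownames(newdata)
  switch(type,
         prob = p,
         class = as.integer(p >= threshold),
         both = data.frame(id = rownames(newdata), prob = unname(p),
                           label = as.integer(p >= threshold),
                           stringsAsFactors = FALSE))
}

#' Hyperparameter grid specification
#'
#' Defaults are the tuning grids of the predictor: iterations in
#' \{250, 100, 500, 1000, 1500, 2000\}, depth 1..10, learning rate in
#' \{0.001, 0.01, 0.03, 0.1, 0.2, 0.3\} — a 6 x 10 x 6 = 360-cell product.
#'
#' @param iterations candidate boosting-round counts.
#' @param depth candidate tree depths.
#' @param learning_rate candidate learning rates.
#' @return a list of class `grid_spec`.
#' @export
grid_spec <- function(iterations = c(250L, 100L, 500L, 1000L, 1500L, 2000L),
                      depth = 1:10,
                      learning_rate = c(0.001, 0.01, 0.03, 0.1, 0.2, 0.3)) {
  stopifnot(length(iterations) >= 1L, length(depth) >= 1L,
            length(learning_rate) >= 1L)
  structure(list(iterations = as.integer(iterations),
                 depth = as.integer(depth),
                 learning_rate = as.numeric(learning_rate)),
            class = "grid_spec")
}

#' Enumerate all grid cells
#'
#' Rows are ordered by (iterations, depth, learning_rate) ascending, which
#' is also the tie-breaking preference of [grid_search()].
#'
#' @param grid a [grid_spec()].
#' @return data frame with one row per candidate configuration.
#' @export
grid_candidates <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  g <- expand.grid(learning_rate = sort(grid$learning_rate),
                   depth = sort(grid$depth),
                   iterations = sort(grid$iterations),
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[order(g$iterations, g$depth, g$learning_rate), c("iterations", "depth", "learning_rate")]
  rownames(g) <- NULL
  g
}

#' Exhaustive grid search by cross-validated AUC
#'
#' Evaluates every cell of the grid with stratified k-fold cross-validation
#' and returns the configuration maximizing mean AUC. Ties prefer fewer
#' iterations, then smaller depth, then smaller learning rate. A cell whose
#' training fails is recorded with `NA` AUC and skipped, not fatal.
#'
#' @inheritParams train_model
#' @param grid a [grid_spec()].
#' @param cv_folds number of cross-validation folds.
#' @param seed fold and training seed.
#' @return the winning [model_config()], with the full results table (one
#'   row per cell, columns of `grid_candidates()` plus `mean_auc`,
#'   `sd_auc`) in attribute `results`.
#' @export
grid_search <- function(X, y, grid = grid_spec(), cv_folds = 10L, seed = 1L) {
  cand <- grid_candidates(grid)
  mean_auc <- sd_auc <- rep(NA_real_, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    cfg <- model_config(iterations = cand$iterations[i],
                        depth = cand$depth[i],
                        learning_rate = cand$learning_rate[i],
                        seed = seed)
    rep_i <- tryCatch(cross_validate(X, y, k = cv_folds, seed = seed,
                                     config = cfg),
                      error = function(e) NULL)
    if (!is.null(rep_i)) {
      mean_auc[i] <- rep_i$mean["AUC"]
      sd_auc[i] <- rep_i$sd["AUC"]
    }
  }
  if (all(is.na(mean_auc))) stop("every grid cell failed", call. = FALSE)
  best <- which.max(mean_auc)   # first max = preferred tie-break order
  out <- model_config(iterations = cand$iterations[best],
                      depth = cand$depth[best],
                      learning_rate = cand$learning_rate[best],
                      seed = seed)
  attr(out, "results") <- cbind(cand, mean_auc = mean_auc, sd_auc = sd_auc)
  out
}

#' Persist a model bundle
#'
#' Writes the booster in xgboost's native binary format and a JSON sidecar
#' (`<path>.json`) with the feature names, training ids and configuration.
#'
#' @param bundle an `m6am_model`.
#' @param path output path for the booster file.
#' @return `path`, invisibly.
#' @export
save_model <- function(bundle, path) {
  stopifnot(inherits(bundle, "m6am_model"))
  raw <- xgboost::xgb.save.raw(bundle$booster)
  writeBin(raw, path)
  sidecar <- list(feature_names = bundle$feature_names,
                  train_ids = bundle$train_ids,
                  config = unclass(bundle$config),
                  package_version = as.character(utils::packageVersion("m6amtools")))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Load a model bundle saved by [save_model()]
#'
#' @param path path passed to [save_model()].
#' @return an `m6am_model`.
#' @export
load_model <- function(path) {
  raw <- readBin(path, what = "raw", n = file.size(path))
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cfg <- do.call(model_config, sidecar$config[c("iterations", "depth",
                                                "learning_rate", "loss_function",
                                                "leaf_estimation_method",
                                                "seed", "nthread")])
  structure(list(booster = xgboost::xgb.load.raw(raw),
                 feature_names = sidecar$feature_names,
                 train_ids = sidecar$train_ids,
                 config = cfg),
            class = "m6am_model")
}
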