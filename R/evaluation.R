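# The six binary-classification metrics, ROC/PR curves, stratified k-fold
# cross-validation and the leakage-guarded independent test.

#' Confusion counts at a probability threshold
#'
#' @param y_true 0/1 labels.
#' @param y_pred 0/1 predicted labels.
#' @return named integer vector (TP, TN, FP, FN).
#' @export
confusion_counts <- function(y_true, y_pred) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  stopifnot(length(y_true) == length(y_pred),
            all(y_true %in% 0:1), all(y_pred %in% 0:1))
  c(TP = sum(y_true == 1L & y_pred == 1L),
    TN = sum(y_true == 0L & y_pred == 0L),
    FP = sum(y_true == 0L & y_pred == 1L),
    FN = sum(y_true == 1L & y_pred == 0L))
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) estimator, equivalent to the trapezoid area
#' under the empirical ROC with ties credited 1/2.
#'
#' @param y_true 0/1 labels, both classes present.
#' @param y_score real-valued scores, larger = more positive.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(y_true, y_score) {
  y_true <- as.integer(y_true)
  stopifnot(length(y_true) == length(y_score))
  n_pos <- sum(y_true == 1L); n_neg <- sum(y_true == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC undefined: y_true contains a single class", call. = FALSE)
  }
  r <- rank(y_score, ties.method = "average")
  (sum(r[y_true == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Compute the six evaluation metrics from scores
#'
#' Thresholded metrics use the confusion table at `threshold`:
#' `Sn = TP/(TP+FN)`, `Sp = TN/(TN+FP)`, `ACC = (TP+TN)/total`,
#' `F1 = 2TP/(2TP+FP+FN)`, and
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`
#' (0 when the denominator vanishes). AUC is threshold-free
#' ([auc_score()]). Requires both classes in `y_true` so that AUC, Sn, Sp
#' and MCC are defined.
#'
#' @inheritParams auc_score
#' @param threshold probability cutoff for the hard labels.
#' @return named numeric vector of class `metric_set` with components ACC,
#'   AUC, Sn, Sp, F1, MCC.
#' @export
compute_metrics <- function(y_true, y_score, threshold = 0.5) {
  y_true <- as.integer(y_true)
  if (length(unique(y_true)) < 2L) {
    stop("metrics undefined: y_true contains a single class", call. = FALSE)
  }
  cc <- confusion_counts(y_true, as.integer(y_score >= threshold))
  metrics_from_counts(cc, auc = auc_score(y_true, y_score))
}

#' Metrics from an explicit confusion table
#'
#' @param counts named vector with TP, TN, FP, FN.
#' @param auc optional AUC to carry through (NA when only hard labels are
#'   available).
#' @return a `metric_set`.
#' @export
metrics_from_counts <- function(counts, auc = NA_real_) {
  # double precision: the MCC denominator overflows integer range
  TP <- as.numeric(counts[["TP"]]); TN <- as.numeric(counts[["TN"]])
  FP <- as.numeric(counts[["FP"]]); FN <- as.numeric(counts[["FN"]])
  total <- TP + TN + FP + FN
  sn <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  sp <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
  f1 <- if (2 * TP + FP + FN > 0) 2 * TP / (2 * TP + FP + FN) else NA_real_
  den <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  mcc <- if (den > 0) (TP * TN - FP * FN) / sqrt(den) else 0
  structure(c(ACC = (TP + TN) / total, AUC = auc, Sn = sn, Sp = sp,
              F1 = f1, MCC = mcc),
            class = "metric_set")
}

#' ROC and precision-recall curve points
#'
#' ROC points run from (0, 0) to (1, 1) over the unique score thresholds
#' (FPR on the abscissa, TPR/sensitivity on the ordinate); the trapezoid
#' area under the returned ROC equals [auc_score()]. PR points use
#' precision `TP/(TP+FP)`, set to 1 at recall 0 by convention.
#'
#' @inheritParams auc_score
#' @return list with data frames `roc` (fpr, tpr, threshold) and `pr`
#'   (recall, precision).
#' @export
curves <- function(y_true, y_score) {
  y_true <- as.integer(y_true)
  n_pos <- sum(y_true == 1L); n_neg <- sum(y_true == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("curves undefined: y_true contains a single class", call. = FALSE)
  }
  ord <- order(y_score, decreasing = TRUE)
  ys <- y_score[ord]; yt <- y_true[ord]
  # collapse tied scores into single thresholds
  last_of_tie <- c(ys[-length(ys)] != ys[-1L], TRUE)
  tp <- cumsum(yt)[last_of_tie]
  n_seen <- seq_along(yt)[last_of_tie]
  fp <- n_seen - tp
  roc <- data.frame(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos),
                    threshold = c(Inf, ys[last_of_tie]))
  pr <- data.frame(recall = c(0, tp / n_pos),
                   precision = c(1, tp / n_seen))
  list(roc = roc, pr = pr)
}

#' Stratified fold assignment
#'
#' Shuffles each class independently under the seed and deals fold indices
#' round-robin, so every fold preserves the class ratio up to rounding.
#'
#' @param y 0/1 labels.
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return integer vector of fold indices in 1..k, aligned with `y`.
#' @export
make_folds <- function(y, k = 10L, seed = 1L) {
  y <- as.integer(y); k <- as.integer(k)
  stopifnot(k >= 2L, length(y) >= k)
  folds <- integer(length(y))
  perms <- .with_seed(seed, lapply(split(seq_along(y), y), function(idx) {
    idx[sample.int(length(idx))]
  }))
  for (idx in perms) {
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  for (f in seq_len(k)) {
    if (length(unique(y[folds == f])) < 2L) {
      stop(sprintf(paste0("fold %d contains a single class; use more data, ",
                          "fewer folds, or another seed"), f), call. = FALSE)
    }
  }
  folds
}

# Evaluate `code` under a fixed seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

#' Stratified k-fold cross-validation
#'
#' Each fold is held out once; the model is trained on the remaining k - 1
#' folds and scored on the held-out fold with [compute_metrics()]. Folds
#' are disjoint, covering and stratified; everything is reproducible under
#' the seed.
#'
#' @param X numeric feature matrix with row and column names.
#' @param y 0/1 labels aligned with `X`.
#' @param k number of folds.
#' @param seed fold and training seed.
#' @param config [model_config()] used by the default model factory.
#' @param model_factory optional function `(X_train, y_train) -> model`
#'   where the model answers `predict(model, X_valid)` with class-1
#'   probabilities; defaults to [train_model()] with `config`.
#' @param threshold cutoff for hard labels.
#' @return list of class `cv_report`: `folds` (k x 6 metric matrix),
#'   `mean`, `sd` (per-metric over folds), `fold_assignment`, and `k`.
#' @export
cross_validate <- function(X, y, k = 10L, seed = 1L,
                           config = model_config(), model_factory = NULL,
                           threshold = 0.5) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  y <- as.integer(y)
  if (is.null(model_factory)) {
    model_factory <- function(Xt, yt) train_model(Xt, yt, config)
  }
  folds <- make_folds(y, k, seed)
  per_fold <- matrix(NA_real_, nrow = k, ncol = 6L,
                     dimnames = list(paste0("fold", seq_len(k)),
                                     c("ACC", "AUC", "Sn", "Sp", "F1", "MCC")))
  for (f in seq_len(k)) {
    hold <- folds == f
    fit <- model_factory(X[!hold, , drop = FALSE], y[!hold])
    p <- predict(fit, X[hold, , drop = FALSE])
    per_fold[f, ] <- unclass(compute_metrics(y[hold], p, threshold))
  }
  structure(list(folds = per_fold,
                 mean = colMeans(per_fold),
                 sd = apply(per_fold, 2L, stats::sd),
                 fold_assignment = folds,
                 k = k),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation\n", x$k))
  out <- sprintf("  %-4s %.3f +/- %.3f\n", names(x$mean), x$mean, x$sd)
  cat(out, sep = "")
  invisible(x)
}

#' Evaluate a trained model on a held-out test set
#'
#' Refuses to run when any test window id also appears among the bundle's
#' training ids — the guard against train/test leakage.
#'
#' @param bundle an `m6am_model`.
#' @param X_test feature matrix of the test windows (rownames = ids).
#' @param y_test 0/1 labels for the test windows.
#' @param threshold cutoff for hard labels.
#' @return a `metric_set`.
#' @export
independent_test <- function(bundle, X_test, y_test, threshold = 0.5) {
  stopifnot(inherits(bundle, "m6am_model"), is.matrix(X_test))
  overlap <- intersect(rownames(X_test), bundle$train_ids)
  if (length(overlap)) {
    stop(sprintf("test set overlaps training set (%d shared id(s), e.g. %s)",
                 length(overlap), paste(utils::head(overlap, 3L), collapse = ", ")),
         call. = FALSE)
  }
  p <- predict(bundle, X_test)
  compute_metrics(y_test, p, threshold)
}
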