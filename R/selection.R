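# Feature-importance ranking with extremely randomized trees, and the
# equidistant (fixed-step) prefix search over the induced feature order.

#' Rank features by extremely-randomized-trees importance
#'
#' Fits an extra-trees ensemble (fully random split points, impurity
#' importance) and returns all features in descending importance order.
#' Ties are broken stably by feature name so the ranking is reproducible.
#'
#' @param X numeric feature matrix with column names; no missing values.
#' @param y binary labels (0/1), both classes present.
#' @param seed integer seed; the same seed yields the identical ranking.
#' @param n_estimators number of trees.
#' @return a data frame of class `importance_ranking` with columns `rank`,
#'   `feature` and `score` (non-negative, non-increasing), plus a `seed`
#'   attribute.
#' @export
rank_features <- function(X, y, seed = 1L, n_estimators = 100L) {
  stopifnot(is.matrix(X), !is.null(colnames(X)))
  if (anyNA(X)) stop("X contains missing values", call. = FALSE)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) {
    stop("y must contain both classes", call. = FALSE)
  }
  fit <- ranger::ranger(
    x = as.data.frame(X), y = factor(y, levels = c(0L, 1L)),
    num.trees = n_estimators, splitrule = "extratrees",
    num.random.splits = 1L, importance = "impurity",
    seed = seed, num.threads = 1L, respect.unordered.factors = FALSE
  )
  score <- fit$variable.importance
  score[score < 0] <- 0           # impurity importance; guard tiny negatives
  ord <- order(-score, names(score), method = "radix")
  out <- data.frame(rank = seq_along(ord),
                    feature = names(score)[ord],
                    score = unname(score[ord]),
                    stringsAsFactors = FALSE)
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("importance_ranking", "data.frame")
  out
}

#' Average rankings computed on several sub-training datasets
#'
#' Normalizes each ranking's scores to sum to 1, averages them per feature,
#' and re-ranks. This is the pooled mode for experiments where each of the
#' balanced sub-training datasets yields its own ranking.
#'
#' @param rankings list of `importance_ranking` objects over the identical
#'   feature set.
#' @return an `importance_ranking` over the averaged normalized scores.
#' @export
average_rankings <- function(rankings) {
  stopifnot(length(rankings) >= 1L)
  feats <- sort(rankings[[1L]]$feature)
  norm <- vapply(rankings, function(r) {
    if (!setequal(r$feature, feats)) {
      stop("rankings cover different feature sets", call. = FALSE)
    }
    s <- stats::setNames(r$score, r$feature)[feats]
    tot <- sum(s)
    if (tot > 0) s / tot else s
  }, numeric(length(feats)))
  score <- rowMeans(norm)
  ord <- order(-score, feats, method = "radix")
  out <- data.frame(rank = seq_along(ord), feature = feats[ord],
                    score = unname(score[ord]), stringsAsFactors = FALSE)
  class(out) <- c("importance_ranking", "data.frame")
  out
}

#' Prefix sizes visited by the equidistant search
#'
#' Sizes step, 2*step, ... up to the feature total; the final prefix is the
#' full feature set even when the total is not a multiple of the step (1120
#' features at step 50 gives 50, 100, ..., 1100, 1120 — 23 evaluations).
#'
#' @param total total feature count.
#' @param step size increment.
#' @return strictly increasing integer vector ending at `total`.
#' @export
subset_schedule <- function(total, step = 50L) {
  total <- as.integer(total); step <- as.integer(step)
  stopifnot(total >= 1L, step >= 1L)
  sizes <- if (step > total) integer(0L) else seq.int(step, total, by = step)
  if (length(sizes) == 0L || sizes[length(sizes)] != total) {
    sizes <- c(sizes, total)
  }
  sizes
}

#' Equidistant search over importance-ranked feature prefixes
#'
#' Evaluates nested prefixes of the ranking (top step, top 2*step, ...,
#' all features) with a cross-validation evaluator and picks the size with
#' the best mean AUC, breaking ties toward the smaller subset.
#'
#' @param ranking an `importance_ranking` covering the columns of `X`.
#' @param X numeric feature matrix (columns named as in `ranking`).
#' @param y binary labels.
#' @param step prefix size increment.
#' @param evaluator function `(X_subset, y) -> ` either a single numeric
#'   (mean AUC) or a list with elements `mean_auc` and optionally `sd_auc`.
#'   Defaults to 5-fold cross-validation of a small boosted-tree model.
#' @param seed seed passed to the default evaluator.
#' @return list of class `subset_search` with elements `sizes`, `mean_auc`,
#'   `sd_auc`, `best_size` and `features` (the winning prefix, in rank
#'   order).
#' @export
equidistant_search <- function(ranking, X, y, step = 50L,
                               evaluator = NULL, seed = 1L) {
  stopifnot(inherits(ranking, "importance_ranking"),
            all(ranking$feature %in% colnames(X)))
  if (is.null(evaluator)) {
    cfg <- model_config(iterations = 50L, depth = 4L, learning_rate = 0.3,
                        seed = seed)
    evaluator <- function(Xs, ys) {
      rep <- cross_validate(Xs, ys, k = 5L, seed = seed, config = cfg)
      list(mean_auc = rep$mean["AUC"], sd_auc = rep$sd["AUC"])
    }
  }
  sizes <- subset_schedule(nrow(ranking), step)
  mean_auc <- sd_auc <- numeric(length(sizes))
  for (s in seq_along(sizes)) {
    feats <- ranking$feature[seq_len(sizes[s])]
    res <- tryCatch(evaluator(X[, feats, drop = FALSE], y), error = function(e) {
      stop(sprintf("evaluator failed at subset size %d: %s",
                   sizes[s], conditionMessage(e)), call. = FALSE)
    })
    if (is.list(res)) {
      mean_auc[s] <- as.numeric(res$mean_auc)
      sd_auc[s] <- if (!is.null(res$sd_auc)) as.numeric(res$sd_auc) else NA_real_
    } else {
      mean_auc[s] <- as.numeric(res)
      sd_auc[s] <- NA_real_
    }
  }
  best <- sizes[which.max(mean_auc)]  # which.max takes the first (smallest) tie
  structure(list(sizes = sizes, mean_auc = mean_auc, sd_auc = sd_auc,
                 best_size = best,
                 features = ranking$feature[seq_len(best)]),
            class = "subset_search")
}

#' Save an importance ranking as TSV
#'
#' @param ranking an `importance_ranking`.
#' @param path output TSV path (columns rank, feature, score).
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  utils::write.table(ranking, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
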