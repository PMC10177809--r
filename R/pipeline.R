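# End-to-end orchestration: simulate/read -> split -> encode -> rank ->
# select -> (tune) -> train -> cross-validate -> aggregate, with every
# artifact persisted under one run directory for exact reruns.

#' Pipeline run configuration
#'
#' @param output_dir directory to create for the run's artifacts.
#' @param dataset an `m6am_dataset`, or `NULL` to simulate one from
#'   `generator`.
#' @param generator a [generator_spec()] used when `dataset` is `NULL`.
#' @param encoder an [encoder_config()].
#' @param n_splits number of balanced sub-training splits.
#' @param selection_step prefix step of the equidistant feature search;
#'   set it to the total feature count to skip the search loop.
#' @param selection_trees trees used for importance ranking.
#' @param cv_folds cross-validation folds.
#' @param model [model_config()] for final training.
#' @param grid optional [grid_spec()]; when supplied, hyperparameters are
#'   tuned on the first sub-training split before final training.
#' @param seed master seed recorded in the manifest; all stage seeds derive
#'   from it.
#' @return a list of class `run_config`.
#' @export
run_config <- function(output_dir,
                       dataset = NULL,
                       generator = generator_spec(),
                       encoder = encoder_config(),
                       n_splits = 10L,
                       selection_step = 50L,
                       selection_trees = 100L,
                       cv_folds = 10L,
                       model = model_config(),
                       grid = NULL,
                       seed = 1L) {
  structure(list(output_dir = output_dir, dataset = dataset,
                 generator = generator, encoder = encoder,
                 n_splits = as.integer(n_splits),
                 selection_step = as.integer(selection_step),
                 selection_trees = as.integer(selection_trees),
                 cv_folds = as.integer(cv_folds),
                 model = model, grid = grid, seed = as.integer(seed)),
            class = "run_config")
}

.stage <- function(name, code) {
  tryCatch(code, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full prediction pipeline
#'
#' Stages: obtain windows (simulated or supplied), build balanced
#' sub-training splits, encode all windows once, rank features per split
#' and average the normalized importances, run the equidistant prefix
#' search (mean cross-validated AUC across splits), optionally grid-search
#' hyperparameters, train one final model per split on the selected
#' features, cross-validate each, and aggregate the per-split means. All
#' numeric reports plus a `MANIFEST.json` (seeds, configuration, stage
#' outputs) are written under `config$output_dir`.
#'
#' @param config a [run_config()].
#' @return list with elements `dataset`, `splits`, `ranking`, `search`,
#'   `model_config`, `models` (one bundle per split), `cv_reports`,
#'   `aggregate` and `output_dir`, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$output_dir, ...)
  seed <- config$seed

  dataset <- .stage("data", {
    ds <- config$dataset
    if (is.null(ds)) {
      spec <- config$generator
      spec$seed <- seed
      ds <- generate_windows(spec)
      write_dataset(ds, out("dataset.fa"), out("labels.tsv"))
    }
    ds
  })

  splits <- .stage("split", {
    s <- make_subtraining_splits(dataset, config$n_splits, seed = seed)
    write_split_manifest(s, out("splits.tsv"))
    s
  })

  X_all <- .stage("encode", encode_matrix(dataset, config$encoder))
  split_xy <- lapply(splits, function(s) {
    list(X = X_all[s$id, , drop = FALSE], y = s$label)
  })

  ranking <- .stage("rank", {
    per_split <- lapply(seq_along(split_xy), function(i) {
      rank_features(split_xy[[i]]$X, split_xy[[i]]$y, seed = seed + i,
                    n_estimators = config$selection_trees)
    })
    r <- if (length(per_split) > 1L) average_rankings(per_split) else per_split[[1L]]
    write_ranking(r, out("ranking.tsv"))
    r
  })

  search <- .stage("select", {
    cv_cfg <- config$model
    evaluator <- function(Xs, ys_unused) {
      aucs <- vapply(split_xy, function(sp) {
        rep_s <- cross_validate(Xs[rownames(sp$X), , drop = FALSE], sp$y,
                                k = config$cv_folds, seed = seed,
                                config = cv_cfg)
        rep_s$mean[["AUC"]]
      }, numeric(1L))
      list(mean_auc = mean(aucs), sd_auc = stats::sd(aucs))
    }
    res <- equidistant_search(ranking, X_all, dataset$label,
                              step = config$selection_step,
                              evaluator = evaluator)
    jsonlite::write_json(res[c("sizes", "mean_auc", "sd_auc", "best_size")],
                         out("search.json"), auto_unbox = TRUE, digits = NA)
    res
  })
  features <- search$features

  final_cfg <- .stage("tune", {
    if (is.null(config$grid)) {
      config$model
    } else {
      sp1 <- split_xy[[1L]]
      grid_search(sp1$X[, features, drop = FALSE], sp1$y, config$grid,
                  cv_folds = config$cv_folds, seed = seed)
    }
  })

  models <- .stage("train", {
    lapply(seq_along(split_xy), function(i) {
      sp <- split_xy[[i]]
      b <- train_model(sp$X[, features, drop = FALSE], sp$y, final_cfg)
      save_model(b, out(sprintf("model_split%02d.ubj", i)))
      b
    })
  })

  cv_reports <- .stage("cv", {
    lapply(split_xy, function(sp) {
      cross_validate(sp$X[, features, drop = FALSE], sp$y,
                     k = config$cv_folds, seed = seed, config = final_cfg)
    })
  })

  agg <- .stage("aggregate", {
    a <- aggregate_metrics(cv_reports)
    utils::write.csv(a, out("metrics.csv"), row.names = FALSE)
    a
  })

  manifest <- list(
    seed = seed,
    n_windows = nrow(dataset),
    n_pos = attr(dataset, "n_pos"),
    n_neg = attr(dataset, "n_neg"),
    n_splits = config$n_splits,
    n_features_total = ncol(X_all),
    selection_step = config$selection_step,
    best_subset_size = search$best_size,
    cv_folds = config$cv_folds,
    model_config = unclass(final_cfg)[c("iterations", "depth", "learning_rate",
                                        "loss_function", "seed")],
    package_version = as.character(utils::packageVersion("m6amtools"))
  )
  jsonlite::write_json(manifest, out("MANIFEST.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(dataset = dataset, splits = splits, ranking = ranking,
                 search = search, model_config = final_cfg, models = models,
                 cv_reports = cv_reports, aggregate = agg,
                 output_dir = config$output_dir))
}
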