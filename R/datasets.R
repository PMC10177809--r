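# Experiment layout for heavily imbalanced benchmarks: split the negatives
# into disjoint shards, pair each shard with the full positive set to form
# balanced sub-training datasets, and aggregate metrics across them.

#' Split negatives into balanced sub-training datasets
#'
#' The negative windows are shuffled (deterministically under the seed) and
#' partitioned into `n_splits` disjoint, exhaustive shards whose sizes
#' differ by at most one; each shard is combined with the identical full
#' positive set. With a 1:10 positive:negative benchmark (3700 vs 37,000)
#' this yields ten ~1:1 sub-training datasets of 3700 + 3700 windows.
#'
#' @param dataset an `m6am_dataset` (see [attach_labels()]).
#' @param n_splits number of negative shards.
#' @param seed shuffle seed; shard membership depends on it, shard sizes do
#'   not.
#' @return list of `n_splits` `m6am_dataset` objects (positives first), with
#'   a `manifest` attribute mapping every window id to its shard.
#' @export
make_subtraining_splits <- function(dataset, n_splits = 10L, seed = 1L) {
  stopifnot(inherits(dataset, "m6am_dataset"))
  n_splits <- as.integer(n_splits)
  if (n_splits < 1L) stop("n_splits must be at least 1", call. = FALSE)
  pos <- dataset[dataset$label == 1L, , drop = FALSE]
  neg <- dataset[dataset$label == 0L, , drop = FALSE]
  if (nrow(neg) < n_splits) {
    stop("fewer negative windows than requested splits", call. = FALSE)
  }
  shuffled <- .with_seed(seed, sample.int(nrow(neg)))
  shard <- rep_len(seq_len(n_splits), nrow(neg))[order(shuffled)]
  splits <- lapply(seq_len(n_splits), function(s) {
    out <- rbind(as.data.frame(pos), as.data.frame(neg[shard == s, , drop = FALSE]))
    rownames(out) <- NULL
    class(out) <- c("m6am_dataset", "data.frame")
    attr(out, "n_pos") <- nrow(pos)
    attr(out, "n_neg") <- sum(shard == s)
    out
  })
  manifest <- data.frame(
    id = c(rep(pos$id, n_splits), neg$id),
    split = c(rep(seq_len(n_splits), each = nrow(pos)), shard),
    role = rep(c("positive", "negative"), c(nrow(pos) * n_splits, nrow(neg))),
    stringsAsFactors = FALSE
  )
  attr(splits, "manifest") <- manifest
  splits
}

#' Write a split manifest as TSV
#'
#' @param splits result of [make_subtraining_splits()].
#' @param path output TSV path (columns id, split, role).
#' @return `path`, invisibly.
#' @export
write_split_manifest <- function(splits, path) {
  utils::write.table(attr(splits, "manifest"), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Aggregate metric sets across sub-training datasets
#'
#' Per-metric mean and standard deviation over the split-level results —
#' the SD is taken over the per-split means (sample SD, n - 1 denominator),
#' not over individual folds.
#'
#' @param results list of `metric_set` vectors (or a list of `cv_report`
#'   objects, in which case each report's fold mean is used).
#' @return data frame with columns `metric`, `mean`, `sd`.
#' @export
aggregate_metrics <- function(results) {
  stopifnot(length(results) >= 1L)
  rows <- lapply(results, function(r) {
    if (inherits(r, "cv_report")) r$mean else unclass(r)
  })
  m <- do.call(rbind, rows)
  data.frame(metric = colnames(m),
             mean = colMeans(m),
             sd = apply(m, 2L, stats::sd),
             row.names = NULL, stringsAsFactors = FALSE)
}
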