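# Reading, validating and normalizing fixed-length RNA windows.
#
# Every downstream encoder assumes a window over {A,C,G,U} whose central base
# is the candidate adenosine, so all validation is concentrated here.

RNA_BASES <- c("A", "C", "G", "U")

#' Normalize a vector of sequences to the RNA alphabet
#'
#' Uppercases, maps the DNA alias T to U, and verifies that only A/C/G/U
#' remain. Ambiguity codes (N, R, Y, ...) are rejected rather than imputed:
#' no encoder defines a value for them.
#'
#' @param x character vector of sequences.
#' @param ids optional record identifiers used in error messages.
#' @return character vector of normalized sequences.
#' @export
normalize_bases <- function(x, ids = NULL) {
  if (is.null(ids)) ids <- as.character(seq_along(x))
  out <- chartr("T", "U", toupper(x))
  bad <- gregexpr("[^ACGU]", out)
  for (i in seq_along(out)) {
    hit <- bad[[i]][1L]
    if (hit != -1L) {
      stop(sprintf(
        "record '%s': invalid character '%s' at position %d (only A/C/G/U/T accepted)",
        ids[i], substr(out[i], hit, hit), hit
      ), call. = FALSE)
    }
  }
  out
}

#' Read fixed-length RNA windows from a FASTA file
#'
#' Each record must be a window of exactly `window_length` nucleotides; with
#' `center_check = TRUE` (the default) the central base — 1-based position
#' `(L + 1) / 2`, i.e. position 21 of a 41-nt window — must be an adenosine,
#' the candidate modification site. Sequences are normalized with
#' [normalize_bases()] (T is accepted and read as U). Record order is
#' preserved.
#'
#' @param path path to a FASTA file (wrapped or unwrapped lines).
#' @param window_length expected window length in nucleotides.
#' @param center_check require an A at the central position. When on,
#'   `window_length` must be odd so that a central position exists.
#' @return a data frame with columns `id` and `seq`, one row per record.
#' @export
read_windows <- function(path, window_length = 41L, center_check = TRUE) {
  stopifnot(length(path) == 1L, file.exists(path))
  window_length <- as.integer(window_length)
  if (window_length < 5L) {
    stop("window_length must be at least 5", call. = FALSE)
  }
  if (center_check && window_length %% 2L == 0L) {
    stop("center_check requires an odd window_length", call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  ids <- names(set)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop(sprintf("FASTA file '%s' contains records without identifiers", path),
         call. = FALSE)
  }
  # keep only the first whitespace-delimited token, as FASTA headers carry
  # free-text descriptions
  ids <- sub("\\s.*$", "", ids)
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate record id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  seqs <- as.character(set)
  wrong <- which(nchar(seqs) != window_length)
  if (length(wrong)) {
    stop(sprintf(
      "record '%s' has length %d, expected %d",
      ids[wrong[1L]], nchar(seqs[wrong[1L]]), window_length
    ), call. = FALSE)
  }
  seqs <- normalize_bases(seqs, ids)
  if (center_check) {
    center <- (window_length + 1L) %/% 2L
    off <- which(substr(seqs, center, center) != "A")
    if (length(off)) {
      stop(sprintf(
        "record '%s': central base (position %d) is '%s', expected 'A'",
        ids[off[1L]], center, substr(seqs[off[1L]], center, center)
      ), call. = FALSE)
    }
  }
  data.frame(id = ids, seq = unname(seqs), stringsAsFactors = FALSE)
}

#' Attach binary labels to a set of windows
#'
#' @param windows data frame with columns `id` and `seq`, as returned by
#'   [read_windows()].
#' @param labels either a named vector of 0/1 labels keyed by window id, or a
#'   data frame with columns `id` and `label`.
#' @return a labeled dataset: a data frame with columns `id`, `seq`, `label`
#'   of class `m6am_dataset`, with attributes `n_pos` and `n_neg`.
#' @export
attach_labels <- function(windows, labels) {
  stopifnot(is.data.frame(windows), all(c("id", "seq") %in% names(windows)))
  if (is.data.frame(labels)) {
    stopifnot(all(c("id", "label") %in% names(labels)))
    labels <- stats::setNames(labels$label, labels$id)
  }
  if (anyDuplicated(names(labels))) {
    stop(sprintf("duplicate id(s) in label mapping: %s",
                 paste(unique(names(labels)[duplicated(names(labels))]),
                       collapse = ", ")), call. = FALSE)
  }
  missing <- setdiff(windows$id, names(labels))
  if (length(missing)) {
    stop(sprintf("no label for window id(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  lab <- as.integer(labels[windows$id])
  if (length(lab) && !all(lab %in% c(0L, 1L))) {
    stop("labels must be 0 or 1", call. = FALSE)
  }
  out <- data.frame(id = windows$id, seq = windows$seq, label = lab,
                    stringsAsFactors = FALSE)
  class(out) <- c("m6am_dataset", "data.frame")
  attr(out, "n_pos") <- sum(lab == 1L)
  attr(out, "n_neg") <- sum(lab == 0L)
  out
}

#' Read a two-column id/label TSV
#'
#' @param path path to a headerless TSV with columns id and label (0/1).
#' @return data frame with columns `id` and `label`.
#' @export
read_labels <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("id", "label"),
                           colClasses = c("character", "integer"))
  tab
}

#' Read a labeled dataset from a positive/negative FASTA pair
#'
#' Alternative labeling mode: all records of `pos_path` are labeled 1, all
#' records of `neg_path` 0.
#'
#' @inheritParams read_windows
#' @param pos_path FASTA of positive windows.
#' @param neg_path FASTA of negative windows.
#' @return an `m6am_dataset` (see [attach_labels()]).
#' @export
read_labeled_fasta <- function(pos_path, neg_path, window_length = 41L,
                               center_check = TRUE) {
  pos <- read_windows(pos_path, window_length, center_check)
  neg <- read_windows(neg_path, window_length, center_check)
  both <- intersect(pos$id, neg$id)
  if (length(both)) {
    stop(sprintf("id(s) present in both classes: %s",
                 paste(both, collapse = ", ")), call. = FALSE)
  }
  windows <- rbind(pos, neg)
  labels <- stats::setNames(rep(c(1L, 0L), c(nrow(pos), nrow(neg))), windows$id)
  attach_labels(windows, labels)
}

#' Write a labeled dataset as FASTA plus label TSV
#'
#' Inverse of [read_windows()] + [attach_labels()]: re-reading the two files
#' reproduces the dataset exactly.
#'
#' @param dataset an `m6am_dataset`.
#' @param fasta_path output FASTA path.
#' @param labels_path optional output path for the id/label TSV.
#' @return `fasta_path`, invisibly.
#' @export
write_dataset <- function(dataset, fasta_path, labels_path = NULL) {
  set <- Biostrings::BStringSet(stats::setNames(dataset$seq, dataset$id))
  Biostrings::writeXStringSet(set, fasta_path)
  if (!is.null(labels_path)) {
    utils::write.table(data.frame(dataset$id, dataset$label),
                       labels_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(fasta_path)
}

#' @export
print.m6am_dataset <- function(x, ...) {
  cat(sprintf("m6am_dataset: %d windows (%d positive, %d negative), length %s nt\n",
              nrow(x), attr(x, "n_pos"), attr(x, "n_neg"),
              if (nrow(x)) nchar(x$seq[1L]) else "?"))
  invisible(x)
}
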