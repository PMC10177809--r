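# Synthetic labeled windows with a controllable class signal, so every
# pipeline stage can be exercised end-to-end without external data.
#
# Positives differ from negatives in two ways, both scaled by effect_size:
# a position-specific motif placed just downstream of the central A
# (detectable by positional encoders: NCP, DBE, Hash, per-position EIIP)
# and a mild GC-ward composition shift at the remaining positions
# (detectable by compositional encoders: k-mer, PseEIIP products). At
# effect_size = 0 both classes are identically distributed.

#' Default planted motif
#'
#' One-hot position weight matrix of the 6-nt consensus GGACUC, placed
#' immediately downstream of the central adenosine.
#'
#' @return 4 x 6 probability matrix (rows A, C, G, U; columns sum to 1).
#' @export
default_motif <- function() {
  consensus <- c("G", "G", "A", "C", "U", "C")
  m <- matrix(0, nrow = 4L, ncol = length(consensus),
              dimnames = list(RNA_BASES, NULL))
  m[cbind(match(consensus, RNA_BASES), seq_along(consensus))] <- 1
  m
}

#' Specification for the synthetic window generator
#'
#' Defaults emulate the shape of the published m6Am benchmark: 41-nt
#' windows with a central A, 3700 positives against 37,000 negatives
#' (a 1:10 imbalance to be handled by negative splitting), uniform
#' background composition, and a strong planted signal (effect_size 0.8).
#'
#' @param n_pos,n_neg class sizes.
#' @param window_length window length (odd, central base forced to A).
#' @param background per-base sampling probabilities (named A/C/G/U,
#'   summing to 1).
#' @param motif probability matrix (4 x motif width) planted in positives
#'   starting one base downstream of the center.
#' @param effect_size in \[0, 1\]: 0 = classes identically distributed,
#'   1 = motif planted deterministically plus full composition shift.
#' @param comp_shift maximum weight of the GC-ward composition shift in
#'   positives (applied as `effect_size * comp_shift`).
#' @param seed integer generation seed.
#' @return a list of class `generator_spec`.
#' @export
generator_spec <- function(n_pos = 3700L, n_neg = 37000L, window_length = 41L,
                           background = c(A = 0.25, C = 0.25, G = 0.25, U = 0.25),
                           motif = default_motif(),
                           effect_size = 0.8, comp_shift = 0.15, seed = 1L) {
  window_length <- as.integer(window_length)
  stopifnot(n_pos >= 0L, n_neg >= 0L, window_length >= 9L,
            window_length %% 2L == 1L,
            effect_size >= 0, effect_size <= 1,
            comp_shift >= 0, comp_shift <= 1)
  stopifnot(setequal(names(background), RNA_BASES), all(background >= 0))
  if (abs(sum(background) - 1) > 1e-8) {
    stop("background probabilities must sum to 1", call. = FALSE)
  }
  stopifnot(is.matrix(motif), nrow(motif) == 4L)
  if (any(motif < 0) || any(abs(colSums(motif) - 1) > 1e-8)) {
    stop("motif columns must be probability vectors", call. = FALSE)
  }
  center <- (window_length + 1L) %/% 2L
  if (center + ncol(motif) > window_length) {
    stop("motif does not fit downstream of the central base", call. = FALSE)
  }
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 window_length = window_length,
                 background = background[RNA_BASES],
                 motif = motif, effect_size = effect_size,
                 comp_shift = comp_shift, seed = as.integer(seed)),
            class = "generator_spec")
}

# per-position base probabilities for one class; a 4 x L matrix
.class_profile <- function(spec, positive) {
  L <- spec$window_length
  center <- (L + 1L) %/% 2L
  prof <- matrix(spec$background, nrow = 4L, ncol = L,
                 dimnames = list(RNA_BASES, NULL))
  if (positive && spec$effect_size > 0) {
    w <- spec$effect_size * spec$comp_shift
    gc_shift <- c(A = 0.15, C = 0.35, G = 0.35, U = 0.15)
    prof[] <- (1 - w) * prof + w * gc_shift
    motif_cols <- center + seq_len(ncol(spec$motif))
    prof[, motif_cols] <- (1 - spec$effect_size) * prof[, motif_cols] +
      spec$effect_size * spec$motif
  }
  prof[, center] <- c(A = 1, C = 0, G = 0, U = 0)
  prof
}

#' Generate a labeled synthetic dataset
#'
#' @param spec a [generator_spec()].
#' @return an `m6am_dataset` with `n_pos` positive windows (ids
#'   `pos_...`) followed by `n_neg` negative windows (ids `neg_...`),
#'   reproducible under the spec's seed.
#' @export
generate_windows <- function(spec = generator_spec()) {
  stopifnot(inherits(spec, "generator_spec"))
  L <- spec$window_length
  sample_class <- function(n, prof) {
    if (n == 0L) return(character(0L))
    chars <- matrix("", nrow = n, ncol = L)
    for (j in seq_len(L)) {
      chars[, j] <- sample(RNA_BASES, n, replace = TRUE, prob = prof[, j])
    }
    apply(chars, 1L, paste, collapse = "")
  }
  seqs <- .with_seed(spec$seed, {
    c(sample_class(spec$n_pos, .class_profile(spec, TRUE)),
      sample_class(spec$n_neg, .class_profile(spec, FALSE)))
  })
  ids <- c(sprintf("pos_%05d", seq_len(spec$n_pos)),
           sprintf("neg_%05d", seq_len(spec$n_neg)))
  windows <- data.frame(id = ids, seq = seqs, stringsAsFactors = FALSE)
  labels <- stats::setNames(rep(c(1L, 0L), c(spec$n_pos, spec$n_neg)), ids)
  attach_labels(windows, labels)
}

#' Small hand-written fixture dataset
#'
#' Twelve fixed 41-nt windows (homopolymer flanks, alternating patterns,
#' motif-bearing windows) shipped with the package, used as stable golden
#' inputs for encoder tests. All windows pass full validation (length 41,
#' central A).
#'
#' @return an `m6am_dataset` of 12 windows.
#' @export
golden_fixture <- function() {
  fa <- system.file("extdata", "golden_windows.fa", package = "m6amtools",
                    mustWork = TRUE)
  tsv <- system.file("extdata", "golden_labels.tsv", package = "m6amtools",
                     mustWork = TRUE)
  attach_labels(read_windows(fa), read_labels(tsv))
}
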