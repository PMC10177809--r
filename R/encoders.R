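# Nine numeric feature-encoding schemes for fixed-length RNA windows, plus
# their concatenation into one named vector per window.
#
# Internally a window is an integer code vector over A=0, C=1, G=2, U=3
# (strict lexicographic order A < C < G < U); every k-mer index is then a
# base-4 number, so lexicographic k-mer order coincides with numeric order.

.codes <- function(seq) {
  m <- match(strsplit(seq, "", fixed = TRUE)[[1L]], RNA_BASES)
  if (anyNA(m)) {
    stop("sequence contains characters outside {A,C,G,U}; run normalize_bases() first",
         call. = FALSE)
  }
  m - 1L
}

# all k-mers over {A,C,G,U} in lexicographic order
.kmer_names <- function(k) {
  grid <- expand.grid(rep(list(RNA_BASES), k), stringsAsFactors = FALSE)
  # expand.grid varies the first factor fastest; reverse for lexicographic
  apply(grid[, rev(seq_len(k)), drop = FALSE], 1L, paste, collapse = "")
}

# base-4 index (0-based) of the k-mer starting at each position 1..L-k+1
.kmer_index <- function(codes, k) {
  L <- length(codes)
  n <- L - k + 1L
  idx <- integer(n)
  for (j in seq_len(k)) {
    idx <- idx * 4L + codes[j:(j + n - 1L)]
  }
  idx
}

.kmer_counts <- function(codes, k) {
  tabulate(.kmer_index(codes, k) + 1L, nbins = 4L^k)
}

#' Electron-ion interaction potential values of the four ribonucleotides
#'
#' Scalar free-electron energies used by the PseEIIP encoder:
#' A = 0.1260, C = 0.1340, G = 0.0806, U = 0.1335.
#'
#' @return named numeric vector over A, C, G, U.
#' @export
eiip_table <- function() {
  c(A = 0.1260, C = 0.1340, G = 0.0806, U = 0.1335)
}

.check_window <- function(seq, min_len = 3L) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) < min_len) {
    stop(sprintf("window of length %d is too short (need at least %d nt)",
                 nchar(seq), min_len), call. = FALSE)
  }
  invisible(seq)
}

#' Pseudo electron-ion interaction potential (PseEIIP) encoding
#'
#' Two parts: the EIIP value of the base at each of the L positions, then for
#' each of the 64 trinucleotides the product `EIIP_xyz * f_xyz`, where
#' `EIIP_xyz = EIIP_x + EIIP_y + EIIP_z` and `f_xyz = N_xyz / (L - 2)` is the
#' trinucleotide frequency. Dimensionality L + 64 (105 for a 41-nt window).
#'
#' @param seq a normalized window (character scalar over A/C/G/U).
#' @param table EIIP value per base, see [eiip_table()].
#' @return named numeric vector of length `nchar(seq) + 64`.
#' @export
encode_pseeiip <- function(seq, table = eiip_table()) {
  .check_window(seq)
  stopifnot(setequal(names(table), RNA_BASES), all(table > 0))
  codes <- .codes(seq)
  L <- length(codes)
  per_pos <- unname(table[RNA_BASES])[codes + 1L]
  tri <- .kmer_names(3L)
  f <- .kmer_counts(codes, 3L) / (L - 2L)
  eiip_xyz <- colSums(matrix(table[RNA_BASES][unlist(strsplit(tri, ""))], nrow = 3L))
  out <- c(per_pos, eiip_xyz * f)
  names(out) <- c(paste0("PseEIIP.pos", seq_len(L)), paste0("PseEIIP.", tri))
  out
}

#' Hash decimal conversion encoding
#'
#' Each sliding k-mer (default k = 2) is read as a k-digit quaternary number
#' with digit values A = 0, G = 1, C = 2, U = 3 and converted to decimal:
#' `s = sum_j 4^(k-j) * h_j`. Dimensionality L - k + 1 (40 for a 41-nt
#' window at k = 2).
#'
#' @inheritParams encode_pseeiip
#' @param k digit count per number.
#' @return named numeric vector of length `nchar(seq) - k + 1`.
#' @export
encode_hash <- function(seq, k = 2L) {
  .check_window(seq, min_len = 2L)
  k <- as.integer(k)
  L <- nchar(seq)
  if (k < 1L || k > L) stop("k must be in [1, window length]", call. = FALSE)
  digit <- c(A = 0L, C = 2L, G = 1L, U = 3L)  # the scheme's own base order
  h <- unname(digit[RNA_BASES])[.codes(seq) + 1L]
  n <- L - k + 1L
  s <- numeric(n)
  for (j in seq_len(k)) s <- s * 4 + h[j:(j + n - 1L)]
  names(s) <- paste0("Hash.p", seq_len(n))
  s
}

#' Dinucleotide binary encoding (DBE)
#'
#' Each of the L - 1 overlapping dinucleotides becomes a 4-bit code, two bits
#' per base: A = (0,0), C = (1,0), G = (1,1), U = (0,1), so that
#' AA -> (0,0,0,0), AC -> (0,0,1,0), AU -> (0,0,0,1), GG -> (1,1,1,1).
#' Dimensionality 4 * (L - 1) (160 for a 41-nt window).
#'
#' @inheritParams encode_pseeiip
#' @return named numeric vector of length `4 * (nchar(seq) - 1)`.
#' @export
encode_dbe <- function(seq) {
  .check_window(seq, min_len = 2L)
  bits <- matrix(c(0, 0,  1, 0,  1, 1,  0, 1), nrow = 2L,
                 dimnames = list(NULL, RNA_BASES))
  codes <- .codes(seq)
  L <- length(codes)
  per_base <- bits[, codes + 1L, drop = FALSE]  # 2 x L
  out <- numeric(4L * (L - 1L))
  for (i in seq_len(L - 1L)) {
    out[(4L * i - 3L):(4L * i)] <- c(per_base[, i], per_base[, i + 1L])
  }
  names(out) <- paste0("DBE.p", rep(seq_len(L - 1L), each = 4L), ".b", 1:4)
  out
}

#' Nucleotide chemical property (NCP) encoding
#'
#' Each base maps to a (ring, amino/keto, hydrogen-bond) triple: x = 1 for
#' purines (A, G), y = 1 for amino bases (A, C), z = 1 for weakly paired
#' bases (A, U); hence A = (1,1,1), C = (0,1,0), G = (1,0,0), U = (0,0,1).
#' Dimensionality 3L (123 for a 41-nt window).
#'
#' @inheritParams encode_pseeiip
#' @return named numeric vector of length `3 * nchar(seq)`.
#' @export
encode_ncp <- function(seq) {
  .check_window(seq, min_len = 1L)
  ncp <- matrix(c(1, 1, 1,  0, 1, 0,  1, 0, 0,  0, 0, 1), nrow = 3L,
                dimnames = list(c("x", "y", "z"), RNA_BASES))
  codes <- .codes(seq)
  out <- as.numeric(ncp[, codes + 1L])
  names(out) <- paste0("NCP.p", rep(seq_along(codes), each = 3L), ".",
                       c("x", "y", "z"))
  out
}

# standardize property rows to zero mean / unit variance across oligomers
.standardize_properties <- function(P) {
  stopifnot(is.matrix(P), !is.null(rownames(P)))
  s <- apply(P, 1L, stats::sd)
  if (any(s == 0)) {
    stop(sprintf("property '%s' is constant across oligonucleotides",
                 rownames(P)[which(s == 0)[1L]]), call. = FALSE)
  }
  (P - rowMeans(P)) / s
}

# Deterministic sequence-derived indices used as the default physicochemical
# property tables. The published property sets behind pseudo-composition
# encoders are not uniquely specified for this task, so these synthetic
# built-ins are plain functions of oligomer composition and order (EIIP sum,
# GC/purine/amino/keto content, nearest-neighbour stacking proxy, base-run
# structure, monophosphate mass). They are standardized before use and fully
# overridable through encoder_config().
.oligo_property_matrix <- function(k, n_properties) {
  mers <- .kmer_names(k)
  chars <- strsplit(mers, "", fixed = TRUE)
  eiip <- eiip_table()
  mass <- c(A = 347.2, C = 323.2, G = 363.2, U = 324.2)  # NMP masses, g/mol
  stack <- outer(eiip, eiip)                              # pair-energy proxy
  fvec <- function(ch) {
    pairs <- cbind(ch[-length(ch)], ch[-1L])
    c(
      eiip_sum   = sum(eiip[ch]),
      gc_content = mean(ch %in% c("G", "C")),
      purine     = mean(ch %in% c("A", "G")),
      amino      = mean(ch %in% c("A", "C")),
      keto       = mean(ch %in% c("G", "U")),
      stacking   = sum(stack[pairs]),
      mass       = sum(mass[ch]),
      transitions = sum(pairs[, 1L] != pairs[, 2L]),
      a_content  = mean(ch == "A"),
      u_content  = mean(ch == "U"),
      first_eiip = unname(eiip[ch[1L]]),
      last_eiip  = unname(eiip[ch[length(ch)]])
    )[seq_len(n_properties)]
  }
  P <- vapply(chars, fvec, numeric(n_properties))
  colnames(P) <- mers
  P
}

#' Default dinucleotide property table (synthetic built-in)
#'
#' Six deterministic composition/order indices per dinucleotide, used by the
#' PseKNC correlation factors. See the package vignette for how these
#' synthetic indices are constructed and how to supply published tables
#' instead.
#'
#' @return 6 x 16 numeric matrix, properties in rows, dinucleotides in
#'   lexicographic columns.
#' @export
default_dinucleotide_properties <- function() {
  .oligo_property_matrix(2L, 6L)
}

#' Default trinucleotide property table (synthetic built-in)
#'
#' Twelve deterministic composition/order indices per trinucleotide, used by
#' the SCPseTNC series-correlation factors.
#'
#' @return 12 x 64 numeric matrix, properties in rows, trinucleotides in
#'   lexicographic columns.
#' @export
default_trinucleotide_properties <- function() {
  .oligo_property_matrix(3L, 12L)
}

#' Encoder configuration
#'
#' Collects the tunable parameters of the nine encoders. The defaults
#' reproduce the printed per-scheme dimensionalities on a 41-nt window:
#' PseEIIP 105, Hash 40, DBE 160, NCP 123, PseKNC `4^k + lambda` (24 at the
#' defaults k = 2, lambda = 8), DNM 48, k-mer 336, SCPseTNC 64 (lambda = 0),
#' Ksnpf 80.
#'
#' @param window_length window length L in nucleotides.
#' @param psekn_k tuple size for the PseKNC frequency part.
#' @param psekn_lambda number of PseKNC correlation tiers (lags); must
#'   satisfy `lambda < L - 1`.
#' @param psekn_omega PseKNC weight of the correlation part, in \[0, 1\].
#' @param psekn_properties dinucleotide property matrix (properties x 16).
#' @param scptnc_lambda number of SCPseTNC lags; must satisfy
#'   `lambda < L - 3`. The default 0 emits the pure 64 trinucleotide
#'   frequencies.
#' @param scptnc_omega SCPseTNC weight of the correlation part, in \[0, 1\].
#' @param scptnc_properties trinucleotide property matrix (properties x 64).
#' @param kmer_ks k values for the k-mer count encoder.
#' @param ksnpf_max_gap largest gap for the k-spaced pair encoder.
#' @return a list of class `encoder_config`.
#' @export
encoder_config <- function(window_length = 41L,
                           psekn_k = 2L,
                           psekn_lambda = 8L,
                           psekn_omega = 0.1,
                           psekn_properties = default_dinucleotide_properties(),
                           scptnc_lambda = 0L,
                           scptnc_omega = 0.1,
                           scptnc_properties = default_trinucleotide_properties(),
                           kmer_ks = c(2L, 3L, 4L),
                           ksnpf_max_gap = 5L) {
  L <- as.integer(window_length)
  stopifnot(L >= 8L, psekn_k >= 1L, psekn_omega >= 0, psekn_omega <= 1,
            scptnc_omega >= 0, scptnc_omega <= 1,
            ksnpf_max_gap >= 1L, all(kmer_ks >= 1L))
  if (psekn_lambda >= L - 1L) {
    stop("psekn_lambda must be smaller than window_length - 1", call. = FALSE)
  }
  if (scptnc_lambda >= L - 3L) {
    stop("scptnc_lambda must be smaller than window_length - 3", call. = FALSE)
  }
  if (L <= ksnpf_max_gap + 1L) {
    stop("window_length must exceed ksnpf_max_gap + 1", call. = FALSE)
  }
  structure(list(
    window_length = L,
    psekn_k = as.integer(psekn_k),
    psekn_lambda = as.integer(psekn_lambda),
    psekn_omega = psekn_omega,
    psekn_properties = psekn_properties,
    scptnc_lambda = as.integer(scptnc_lambda),
    scptnc_omega = scptnc_omega,
    scptnc_properties = scptnc_properties,
    kmer_ks = as.integer(kmer_ks),
    ksnpf_max_gap = as.integer(ksnpf_max_gap)
  ), class = "encoder_config")
}

#' Pseudo k-tuple nucleotide composition (PseKNC)
#'
#' First `4^k` components are normalized k-tuple frequencies; the last
#' `lambda` components are lag-j correlation factors `theta_j`, the mean over
#' the window of the squared property distance between dinucleotides j apart,
#' weighted by `omega`. All components share one denominator, so the vector
#' sums to 1.
#'
#' @inheritParams encode_pseeiip
#' @param cfg an [encoder_config()].
#' @return named numeric vector of length `4^k + lambda`.
#' @export
encode_psekn <- function(seq, cfg = encoder_config(nchar(seq))) {
  .check_window(seq)
  codes <- .codes(seq)
  L <- length(codes)
  k <- cfg$psekn_k
  lambda <- cfg$psekn_lambda
  if (lambda >= L - 1L) stop("psekn_lambda must be < L - 1", call. = FALSE)
  if (lambda > 0L && (is.null(cfg$psekn_properties) ||
                      nrow(cfg$psekn_properties) == 0L)) {
    stop("psekn_lambda > 0 requires a non-empty dinucleotide property table",
         call. = FALSE)
  }
  f <- .kmer_counts(codes, k)
  f <- f / sum(f)
  theta <- numeric(lambda)
  if (lambda > 0L) {
    P <- .standardize_properties(cfg$psekn_properties)
    di <- .kmer_index(codes, 2L) + 1L   # dinucleotide at positions 1..L-1
    mu <- nrow(P)
    for (j in seq_len(lambda)) {
      i <- seq_len(L - j - 1L)
      d <- P[, di[i], drop = FALSE] - P[, di[i + j], drop = FALSE]
      theta[j] <- mean(colSums(d^2) / mu)
    }
  }
  denom <- sum(f) + cfg$psekn_omega * sum(theta)
  out <- c(f, cfg$psekn_omega * theta) / denom
  names(out) <- c(paste0("PseKNC.f.", .kmer_names(k)),
                  if (lambda > 0L) paste0("PseKNC.theta", seq_len(lambda)))
  out
}

#' Dinucleotide numerical mapping (DNM)
#'
#' For each of the 16 dinucleotides, three occurrence statistics over the
#' L - 1 dinucleotide positions i: the count `n = sum f(t_i)`, the mean
#' occurrence position `u = sum i f(t_i) / n`, and the normalized positional
#' variance `D2 = sum (i - u)^2 f(t_i) / (n (L - 1))`. A dinucleotide that
#' never occurs is emitted as (0, 0, 0). Dimensionality 48.
#'
#' @inheritParams encode_pseeiip
#' @return named numeric vector of length 48.
#' @export
encode_dnm <- function(seq) {
  .check_window(seq, min_len = 2L)
  codes <- .codes(seq)
  L <- length(codes)
  di <- .kmer_index(codes, 2L)
  out <- numeric(48L)
  for (d in 0:15) {
    pos <- which(di == d)
    n <- length(pos)
    if (n > 0L) {
      u <- sum(pos) / n
      D2 <- sum((pos - u)^2) / (n * (L - 1L))
      out[3L * d + 1:3] <- c(n, u, D2)
    }
  }
  names(out) <- paste0("DNM.", rep(.kmer_names(2L), each = 3L), ".",
                       c("n", "u", "D2"))
  out
}

#' K-mer occurrence counts
#'
#' Raw sliding-window counts of each k-mer, for each k in `ks`, k-mers in
#' lexicographic order. Dimensionality `sum(4^ks)` (336 for ks = 2,3,4).
#'
#' @inheritParams encode_pseeiip
#' @param ks k values.
#' @return named numeric vector of length `sum(4^ks)`.
#' @export
encode_kmer <- function(seq, ks = c(2L, 3L, 4L)) {
  .check_window(seq, min_len = max(ks))
  codes <- .codes(seq)
  if (max(ks) > length(codes)) stop("k exceeds window length", call. = FALSE)
  out <- unlist(lapply(as.integer(ks), function(k) {
    stats::setNames(as.numeric(.kmer_counts(codes, k)),
                    paste0("Kmer", k, ".", .kmer_names(k)))
  }))
  out
}

#' Series correlation pseudo trinucleotide composition (SCPseTNC)
#'
#' First 64 components are normalized trinucleotide frequencies; then, for
#' each lag m = 1..lambda and each of the Lambda properties, a
#' series-correlation factor `theta = mean_i P(tri_i) * P(tri_{i+m})` over
#' i = 1..(L - m - 3), weighted by `omega` and sharing the common
#' denominator. Dimensionality `64 + lambda * Lambda`; the default
#' configuration (lambda = 0) emits exactly the 64 frequencies.
#'
#' @inheritParams encode_psekn
#' @return named numeric vector of length `64 + lambda * n_properties`.
#' @export
encode_scptnc <- function(seq, cfg = encoder_config(nchar(seq))) {
  .check_window(seq, min_len = 4L)
  codes <- .codes(seq)
  L <- length(codes)
  lambda <- cfg$scptnc_lambda
  if (lambda >= L - 3L) stop("scptnc_lambda must be < L - 3", call. = FALSE)
  f <- .kmer_counts(codes, 3L)
  f <- f / sum(f)
  theta <- numeric(0L)
  theta_names <- character(0L)
  if (lambda > 0L) {
    P <- .standardize_properties(cfg$scptnc_properties)
    tri <- .kmer_index(codes, 3L) + 1L  # trinucleotide at positions 1..L-2
    for (m in seq_len(lambda)) {
      i <- seq_len(L - m - 3L)
      J <- P[, tri[i], drop = FALSE] * P[, tri[i + m], drop = FALSE]
      theta <- c(theta, rowMeans(J))
      theta_names <- c(theta_names,
                       paste0("SCPseTNC.theta.lag", m, ".", rownames(P)))
    }
  }
  denom <- sum(f) + cfg$scptnc_omega * sum(theta)
  out <- c(f, cfg$scptnc_omega * theta) / denom
  names(out) <- c(paste0("SCPseTNC.f.", .kmer_names(3L)), theta_names)
  out
}

#' K-spaced nucleotide pair frequency (Ksnpf)
#'
#' For each gap k = 1..max_gap and each ordered base pair (n1, n2), the
#' frequency `S / (L - k - 1)` of positions i with base n1 at i and base n2
#' at i + k + 1 (k intervening bases). Dimensionality `16 * max_gap` (80 at
#' max_gap = 5).
#'
#' @inheritParams encode_pseeiip
#' @param max_gap largest gap considered.
#' @return named numeric vector of length `16 * max_gap`.
#' @export
encode_ksnpf <- function(seq, max_gap = 5L) {
  .check_window(seq, min_len = max_gap + 2L)
  codes <- .codes(seq)
  L <- length(codes)
  if (L <= max_gap + 1L) stop("window too short for max_gap", call. = FALSE)
  pairs <- .kmer_names(2L)
  out <- numeric(16L * max_gap)
  nm <- character(16L * max_gap)
  for (k in seq_len(max_gap)) {
    n <- L - k - 1L
    i <- seq_len(n)
    idx <- 4L * codes[i] + codes[i + k + 1L]
    out[(16L * (k - 1L)) + 1:16] <- tabulate(idx + 1L, nbins = 16L) / n
    nm[(16L * (k - 1L)) + 1:16] <- paste0("Ksnpf.gap", k, ".", pairs)
  }
  stats::setNames(out, nm)
}

#' Concatenate all nine encodings of one window
#'
#' Fixed block order: PseEIIP, Hash, DBE, NCP, PseKNC, DNM, Kmer, SCPseTNC,
#' Ksnpf. Feature names are globally unique (each block carries its scheme
#' prefix) and the total dimensionality is identical for all windows of
#' equal length — 980 at the default configuration on 41-nt windows.
#'
#' @inheritParams encode_psekn
#' @return named numeric vector.
#' @export
encode_all <- function(seq, cfg = encoder_config(nchar(seq))) {
  if (nchar(seq) != cfg$window_length) {
    stop(sprintf("window length %d does not match configured length %d",
                 nchar(seq), cfg$window_length), call. = FALSE)
  }
  c(encode_pseeiip(seq),
    encode_hash(seq),
    encode_dbe(seq),
    encode_ncp(seq),
    encode_psekn(seq, cfg),
    encode_dnm(seq),
    encode_kmer(seq, cfg$kmer_ks),
    encode_scptnc(seq, cfg),
    encode_ksnpf(seq, cfg$ksnpf_max_gap))
}

#' Encode a set of windows into a feature matrix
#'
#' @param x an `m6am_dataset`, a data frame with a `seq` column, or a
#'   character vector of windows (optionally named by id).
#' @param cfg an [encoder_config()].
#' @return numeric matrix, one row per window (rownames = ids), one column
#'   per feature.
#' @export
encode_matrix <- function(x, cfg = encoder_config()) {
  if (is.data.frame(x)) {
    seqs <- stats::setNames(x$seq, x$id)
  } else {
    seqs <- x
    if (is.null(names(seqs))) names(seqs) <- paste0("w", seq_along(seqs))
  }
  if (!length(seqs)) stop("no windows to encode", call. = FALSE)
  first <- encode_all(seqs[[1L]], cfg)
  out <- matrix(0, nrow = length(seqs), ncol = length(first),
                dimnames = list(names(seqs), names(first)))
  out[1L, ] <- first
  if (length(seqs) > 1L) {
    for (i in 2L:length(seqs)) out[i, ] <- encode_all(seqs[[i]], cfg)
  }
  out
}

#' Write a feature matrix as CSV
#'
#' One row per window id, header row of globally unique feature names.
#'
#' @param X feature matrix from [encode_matrix()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(X, path) {
  utils::write.csv(as.data.frame(X), path, row.names = TRUE)
  invisible(path)
}
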