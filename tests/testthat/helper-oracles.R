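# Brute-force oracles and small fixture builders shared across tests.
# Oracles deliberately use naive substring enumeration, independent of the
# base-4 index arithmetic inside the encoders.

BASES <- c("A", "C", "G", "U")

random_window <- function(L, center_a = FALSE) {
  s <- sample(BASES, L, replace = TRUE)
  if (center_a) s[(L + 1L) %/% 2L] <- "A"
  paste(s, collapse = "")
}

all_kmers <- function(k) {
  g <- expand.grid(rep(list(BASES), k), stringsAsFactors = FALSE)
  sort(apply(g, 1L, paste, collapse = ""))
}

# sliding-window occurrence counts by direct substring comparison
bf_kmer_counts <- function(seq, k) {
  L <- nchar(seq)
  subs <- vapply(seq_len(L - k + 1L), function(i) substr(seq, i, i + k - 1L), "")
  vapply(all_kmers(k), function(m) sum(subs == m), numeric(1L))
}

# pair counts at gap k (k intervening bases) by direct position scan
bf_ksnpf <- function(seq, gap) {
  L <- nchar(seq)
  ch <- strsplit(seq, "")[[1L]]
  pairs <- as.vector(t(outer(BASES, BASES, paste0)))
  n <- L - gap - 1L
  counts <- vapply(pairs, function(p) {
    b1 <- substr(p, 1L, 1L); b2 <- substr(p, 2L, 2L)
    sum(ch[seq_len(n)] == b1 & ch[seq_len(n) + gap + 1L] == b2)
  }, numeric(1L))
  counts / n
}

# dinucleotide occurrence statistics by direct looping over positions
bf_dnm <- function(seq) {
  L <- nchar(seq)
  ch <- strsplit(seq, "")[[1L]]
  di <- paste0(ch[-L], ch[-1L])
  out <- numeric(0L)
  for (d in all_kmers(2L)) {
    pos <- which(di == d)
    n <- length(pos)
    if (n == 0L) {
      out <- c(out, 0, 0, 0)
    } else {
      u <- mean(pos)
      out <- c(out, n, u, sum((pos - u)^2) / (n * (L - 1L)))
    }
  }
  out
}

# small numeric dataset with a planted linear signal in the first
# `n_signal` features; remaining features are pure noise
planted_features <- function(n = 200L, n_signal = 5L, n_noise = 20L,
                             noise_sd = 0.05) {
  y <- rep(c(0L, 1L), length.out = n)
  X <- cbind(
    matrix(rep(y, n_signal), ncol = n_signal) +
      matrix(rnorm(n * n_signal, sd = noise_sd), ncol = n_signal),
    matrix(rnorm(n * n_noise), ncol = n_noise)
  )
  colnames(X) <- c(sprintf("sig%02d", seq_len(n_signal)),
                   sprintf("noise%02d", seq_len(n_noise)))
  rownames(X) <- sprintf("s%04d", seq_len(n))
  list(X = X, y = y)
}
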