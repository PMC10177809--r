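polyA <- strrep("A", 41)

test_that("per-position EIIP values and trinucleotide products are exact", {
  v <- encode_pseeiip(paste0("G", strrep("A", 40)))
  expect_equal(unname(v[1]), 0.0806)          # G leads the window
  expect_equal(unname(v[2]), 0.1260)

  v <- encode_pseeiip(polyA)
  expect_equal(unname(v["PseEIIP.AAA"]), 3 * 0.1260 * 1)
  other_tri <- setdiff(grep("^PseEIIP\\.[ACGU]{3}$", names(v), value = TRUE),
                       "PseEIIP.AAA")
  expect_true(all(v[other_tri] == 0))
  # trinucleotide frequencies always sum to 1
  set.seed(21)
  w <- random_window(41)
  tri_part <- encode_pseeiip(w)[42:105]
  eiip_sums <- vapply(strsplit(sub("PseEIIP\\.", "", names(tri_part)), ""),
                      function(ch) sum(eiip_table()[ch]), numeric(1))
  expect_equal(sum(tri_part / eiip_sums), 1)
})

test_that("hash encoder converts two-digit quaternary numbers with the A0/G1/C2/U3 map", {
  expect_equal(unname(encode_hash("GUAAAAAA")[1]), 7)   # 4*1 + 3
  expect_equal(unname(encode_hash("AAAAAAAA")), rep(0, 7))
  expect_equal(unname(encode_hash("UUUUUUUU")), rep(15, 7))
  # every sliding pair independently, against direct digit arithmetic
  set.seed(22)
  w <- random_window(15)
  digits <- c(A = 0, G = 1, C = 2, U = 3)[strsplit(w, "")[[1]]]
  expect_equal(unname(encode_hash(w, k = 2)),
               4 * digits[-15] + digits[-1], ignore_attr = TRUE)
  expect_error(encode_hash("ACGU", k = 5), "k must be")
})

test_that("DBE and NCP emit the fixed per-dinucleotide and per-base codes", {
  expect_equal(unname(encode_dbe("AA")), c(0, 0, 0, 0))
  expect_equal(unname(encode_dbe("AU")), c(0, 0, 0, 1))
  expect_equal(unname(encode_dbe("AC")), c(0, 0, 1, 0))
  expect_equal(unname(encode_dbe("GG")), c(1, 1, 1, 1))

  expect_equal(unname(encode_ncp("A")), c(1, 1, 1))
  expect_equal(unname(encode_ncp("C")), c(0, 1, 0))
  expect_equal(unname(encode_ncp("G")), c(1, 0, 0))
  expect_equal(unname(encode_ncp("U")), c(0, 0, 1))
  # x distinguishes purines from pyrimidines at every position
  set.seed(23)
  w <- random_window(41)
  x <- encode_ncp(w)[seq(1, 123, by = 3)]
  expect_equal(unname(x),
               as.numeric(strsplit(w, "")[[1]] %in% c("A", "G")))
})

test_that("PseKNC components sum to 1 and lose the correlation part on uniform windows", {
  cfg <- encoder_config()
  set.seed(24)
  for (i in 1:5) {
    v <- encode_psekn(random_window(41), cfg)
    expect_length(v, 16 + cfg$psekn_lambda)
    expect_equal(sum(v), 1)
    expect_true(all(v >= 0))
  }
  # poly-A: all dinucleotides identical, property distance 0, theta = 0
  v <- encode_psekn(polyA, cfg)
  expect_equal(unname(v[grep("theta", names(v))]), rep(0, cfg$psekn_lambda))
  expect_equal(unname(v["PseKNC.f.AA"]), 1)
  # lambda = 0 reduces to plain normalized dinucleotide frequencies
  cfg0 <- encoder_config(psekn_lambda = 0)
  set.seed(25)
  w <- random_window(41)
  expect_equal(unname(encode_psekn(w, cfg0)),
               unname(bf_kmer_counts(w, 2) / 40))
})

test_that("DNM matches direct positional statistics and handles absent dinucleotides", {
  v <- encode_dnm(polyA)
  expect_equal(unname(v[c("DNM.AA.n", "DNM.AA.u")]), c(40, 20.5))
  expect_equal(unname(v["DNM.CG.n"]), 0)
  expect_equal(unname(v[c("DNM.CG.u", "DNM.CG.D2")]), c(0, 0))
  set.seed(26)
  for (i in 1:10) {
    w <- random_window(sample(8:15, 1))
    expect_equal(unname(encode_dnm(w)), bf_dnm(w))
  }
})

test_that("k-mer counts conserve totals and match brute-force enumeration", {
  v <- encode_kmer(polyA)
  expect_equal(unname(v["Kmer4.AAAA"]), 38)
  expect_equal(sum(encode_kmer(polyA, ks = 2)), 40)
  set.seed(27)
  for (i in 1:10) {
    w <- random_window(sample(8:15, 1))
    for (k in 2:3) {
      expect_equal(unname(encode_kmer(w, ks = k)), unname(bf_kmer_counts(w, k)))
    }
    expect_equal(sum(encode_kmer(w, ks = 2)), nchar(w) - 1)
  }
})

test_that("SCPseTNC defaults to normalized trinucleotide frequencies and adds lag terms", {
  set.seed(28)
  w <- random_window(41)
  v <- encode_scptnc(w)
  expect_length(v, 64)
  expect_equal(unname(v), unname(bf_kmer_counts(w, 3) / 39))
  expect_equal(sum(v), 1)
  # with lags: dimensionality 64 + lambda * Lambda, components still sum to 1
  cfg <- encoder_config(scptnc_lambda = 2)
  v2 <- encode_scptnc(w, cfg)
  expect_length(v2, 64 + 2 * nrow(cfg$scptnc_properties))
  expect_equal(sum(v2), 1)
  # uniform window: every lag-m product equals P(AAA)^2 within each property
  vA <- encode_scptnc(polyA, cfg)
  th <- vA[grep("theta", names(vA))]
  lag1 <- th[grep("lag1", names(th))]
  lag2 <- th[grep("lag2", names(th))]
  expect_equal(unname(lag1), unname(lag2))
})

test_that("Ksnpf frequencies match direct gap-pair scans", {
  v <- encode_ksnpf(polyA)
  expect_equal(unname(v["Ksnpf.gap1.AA"]), 1)      # 39/39
  expect_true(all(v[setdiff(names(v), paste0("Ksnpf.gap", 1:5, ".AA"))] == 0))
  set.seed(29)
  for (i in 1:10) {
    w <- random_window(sample(8:15, 1))
    for (g in 1:3) {
      got <- encode_ksnpf(w, max_gap = g)
      expect_equal(unname(got[(16 * (g - 1)) + 1:16]), unname(bf_ksnpf(w, g)))
    }
  }
})

test_that("dimensional contracts hold across window lengths, not only 41", {
  set.seed(30)
  for (L in c(9, 12, 17, 25, 41)) {
    w <- random_window(L)
    cfg <- encoder_config(window_length = L, psekn_lambda = 3)
    expect_length(encode_pseeiip(w), L + 64)
    expect_length(encode_hash(w), L - 1)
    expect_length(encode_dbe(w), 4 * (L - 1))
    expect_length(encode_ncp(w), 3 * L)
    expect_length(encode_psekn(w, cfg), 16 + 3)
    expect_length(encode_dnm(w), 48)
    expect_length(encode_kmer(w), 336)
    expect_length(encode_scptnc(w, cfg), 64)
    expect_length(encode_ksnpf(w), 80)
  }
})

test_that("composition blocks are permutation invariant; positional blocks are not", {
  set.seed(31)
  w <- random_window(41)
  ch <- strsplit(w, "")[[1]]
  repeat {  # a shuffle that actually changes the string
    perm <- paste(sample(ch), collapse = "")
    if (perm != w) break
  }
  expect_equal(encode_kmer(w, ks = 1), encode_kmer(perm, ks = 1))
  tri <- function(s) encode_pseeiip(s)[42:105]
  expect_false(isTRUE(all.equal(tri(w), tri(perm))))  # trinucleotides reshuffle
  expect_false(isTRUE(all.equal(encode_ncp(w), encode_ncp(perm))))
  expect_false(isTRUE(all.equal(encode_dbe(w), encode_dbe(perm))))
  expect_false(isTRUE(all.equal(encode_hash(w), encode_hash(perm))))
  # single-base composition is preserved, so per-position EIIP sums agree
  expect_equal(sum(encode_pseeiip(w)[1:41]), sum(encode_pseeiip(perm)[1:41]))
})

test_that("encode_all concatenates deterministically with unique global names", {
  set.seed(32)
  w <- random_window(41, center_a = TRUE)
  v1 <- encode_all(w)
  v2 <- encode_all(w)
  expect_identical(v1, v2)
  expect_false(anyDuplicated(names(v1)) > 0)
  expect_length(v1, 892 + 16 + encoder_config()$psekn_lambda + 64)
  # T-spelled DNA input encodes identically after normalization
  dna <- chartr("U", "T", w)
  expect_identical(encode_all(normalize_bases(dna)), v1)
  # frequency-type blocks stay within [0, 1]
  freq <- v1[grep("^(Ksnpf|PseKNC|SCPseTNC\\.f)", names(v1))]
  expect_true(all(freq >= 0 & freq <= 1))
})

test_that("encode_matrix builds a named windows-by-features matrix", {
  ds <- golden_fixture()
  X <- encode_matrix(ds)
  expect_equal(rownames(X), ds$id)
  expect_equal(ncol(X), length(encode_all(ds$seq[1])))
  expect_false(anyNA(X))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_matrix(X, path)
  back <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  expect_equal(back, X)
})
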