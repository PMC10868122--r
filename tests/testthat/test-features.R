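test_that("tokenize produces lexicographic overlapping k-mer codes", {
  expect_equal(tokenize("ACGU", 1), 1:4)
  t2 <- tokenize("ACGU", 2)
  expect_length(t2, 3L)
  expect_equal(kmer_names(2)[t2], c("AC", "CG", "GU"))
  expect_length(tokenize(random_window_seq(41), 3), 39L)
  for (k in 1:3) expect_equal(tokenize(strrep("A", 5), k)[1], 1L)
  expect_error(tokenize("ACGU", 4), "level")
})

test_that("kmer codes invert through kmer_names for random windows", {
  set.seed(21)
  for (i in 1:20) {
    s <- random_window_seq(41)
    for (k in 1:3) {
      toks <- tokenize(s, k)
      mers <- substring(s, seq_len(41 - k + 1), seq_len(41 - k + 1) + k - 1)
      expect_identical(kmer_names(k)[toks], mers)
    }
  }
})

test_that("sequence_matrix fills row-major into the smallest square", {
  m <- sequence_matrix(tokenize(random_window_seq(41), 1))
  expect_equal(dim(m), c(7L, 7L))
  expect_equal(sum(m == 0), 8L)
  m4 <- sequence_matrix(c(3L, 1L, 4L, 2L))
  expect_equal(m4, matrix(c(3, 1, 4, 2), 2, 2, byrow = TRUE))
  expect_equal(sequence_matrix(c(9L, 5L))[1, 1], 9)
  expect_error(sequence_matrix(integer(0)), "empty")
})

test_that("prim accumulates forward pairwise distances", {
  V <- prim(tokenize("AC", 1), 1)
  expect_equal(V[1, 2], 1)
  expect_equal(sum(V), 1)
  V3 <- prim(tokenize("AAA", 1), 1)
  expect_equal(V3[1, 1], 4)  # (2-1)+(3-1)+(3-2)
  expect_equal(prim(1L, 1), matrix(0, 4, 4))
  set.seed(22)
  for (i in 1:10) {
    s <- random_window_seq(41)
    for (k in 1:2) {
      toks <- tokenize(s, k)
      expect_equal(prim(toks, k), oracle_prim(toks, 4^k))
    }
  }
})

test_that("rprim is prim of the reversed symbols", {
  expect_equal(rprim("AC", 1)[2, 1], 1)
  pal <- "ACGAGCA"  # equals its own reversal
  expect_equal(rprim(pal, 1), prim(tokenize(pal, 1), 1))
  set.seed(23)
  s <- random_window_seq(41)
  toks_rev <- tokenize(reverse_window(s), 2)
  expect_equal(rprim(s, 2), oracle_prim(toks_rev, 16))
})

test_that("frequency vector counts overlapping k-mers", {
  fv <- frequency_vector(strrep("A", 41))
  expect_equal(unname(fv["A"]), 41L)
  expect_equal(unname(fv["AA"]), 40L)
  expect_equal(unname(fv["AAA"]), 39L)
  expect_equal(sum(fv) , 41L + 40L + 39L)
  set.seed(24)
  for (i in 1:5) {
    s <- random_window_seq(41)
    fv <- frequency_vector(s)
    expect_equal(sum(fv[5:20]), 40L)  # di-counts sum to L-1
    for (kmer in c("A", "U", "AG", "CGU", "UUU")) {
      expect_equal(unname(fv[kmer]), oracle_kmer_count(s, kmer))
    }
  }
})

test_that("aapiv/raapiv sum occurrence start positions", {
  v <- aapiv("ACGA")$k1
  expect_equal(unname(v), c(5, 2, 3, 0))
  # reverse-direction value equals sum of (L+1-p) over forward positions
  set.seed(25)
  for (i in 1:10) {
    s <- random_window_seq(41)
    fwd <- aapiv(s); rev <- raapiv(s)
    expect_equal(sum(fwd$k1), 41 * 42 / 2)
    expect_equal(sum(rev$k1), 41 * 42 / 2)
    chars <- strsplit(s, "")[[1]]
    for (b in seq_along(BASES)) {
      pos <- which(chars == BASES[b])
      expect_equal(unname(rev$k1[b]), sum(41 + 1 - pos))
    }
    for (kmer in c("AC", "GG", "UAU")) {
      lvl <- paste0("k", nchar(kmer))
      expect_equal(unname(fwd[[lvl]][kmer]), oracle_position_sum(s, kmer))
    }
  }
  pal <- "ACGAGCA"
  expect_equal(aapiv(pal), raapiv(pal))
})

test_that("partition identities hold across many random windows", {
  set.seed(26)
  for (i in 1:500) {
    W <- sample(c(7L, 21L, 41L), 1)
    s <- random_window_seq(W)
    fv <- frequency_vector(s)
    expect_equal(sum(fv[1:4]), W)
    expect_equal(sum(fv[5:20]), W - 1L)
    expect_equal(sum(fv[21:84]), W - 2L)
    expect_equal(sum(aapiv(s)$k1), W * (W + 1) / 2)
    expect_equal(sum(raapiv(s)$k1), W * (W + 1) / 2)
  }
})

test_that("assemble_features yields the frozen 522-value layout", {
  w <- validate_window(random_window_seq(41), id = "x")
  fv <- assemble_features(w)
  expect_length(fv, 522L)
  expect_true(all(is.finite(fv)))
  grp <- rle(sub("\\..*$", "", names(fv)))
  expect_equal(grp$values,
               c("PRIM", "RPRIM", "FV", "AAPIV", "RAAPIV", "SEQMAT"))
  expect_equal(grp$lengths, unname(feature_groups()))
  expect_identical(assemble_features(w), assemble_features(w))
})

test_that("feature groups decompose into their defining parts", {
  w <- validate_window(random_window_seq(41))
  fv <- assemble_features(w, u = 0.5, v = 1)
  expect_equal(unname(fv[1:30]),
               unname(moment_set(prim(tokenize(w, 1), 1), u = 0.5, v = 1)))
  expect_equal(unname(fv[181:264]), unname(as.numeric(frequency_vector(w))))
  expect_equal(unname(fv[265:268]), unname(aapiv(w)$k1))
  expect_equal(unname(fv[349:352]), unname(raapiv(w)$k1))
  expect_equal(unname(fv[433:462]),
               unname(moment_set(sequence_matrix(tokenize(w, 1)),
                                 u = 0.5, v = 1)))
})

test_that("a near-degenerate window encodes finite with forced FV support", {
  s <- paste0(strrep("U", 20), "A", strrep("U", 20))
  fv <- assemble_features(s)
  expect_true(all(is.finite(fv)))
  counts <- frequency_vector(s)
  nz <- names(counts[counts > 0])
  expect_setequal(nz, c("A", "U", "AU", "UA", "UU", "AUU", "UAU",
                        "UUA", "UUU"))
  expect_equal(unname(counts["UU"]), 38L)
  expect_equal(unname(counts["UUU"]), 36L)
})

test_that("feature_matrix stacks windows with ids and labels", {
  set.seed(27)
  win <- random_windows(4)
  win[[1]]$label <- "positive"
  X <- feature_matrix(win)
  expect_equal(dim(X), c(4L, 522L))
  expect_equal(rownames(X), paste0("w", 1:4))
  expect_equal(attr(X, "label")[1], "positive")
})
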