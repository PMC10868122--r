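# Independent brute-force oracles and fixture builders. These stay
# deliberately naive (explicit double loops) so they cannot share bugs
# with the vectorized implementations they check.

BASES <- c("A", "C", "G", "U")

random_window_seq <- function(W = 41L) {
  b <- sample(BASES, W, replace = TRUE)
  b[(W + 1L) / 2L] <- "A"
  paste(b, collapse = "")
}

random_windows <- function(n, W = 41L) {
  lapply(seq_len(n), function(i) {
    validate_window(random_window_seq(W), W = W, id = paste0("w", i))
  })
}

oracle_raw_moment <- function(M, j, k) {
  s <- 0
  for (c in seq_len(nrow(M))) for (d in seq_len(ncol(M)))
    s <- s + c^j * d^k * M[c, d]
  unname(s)
}

oracle_centroid <- function(M) {
  num_x <- 0; num_y <- 0; tot <- 0
  for (c in seq_len(nrow(M))) for (d in seq_len(ncol(M))) {
    num_x <- num_x + c * M[c, d]
    num_y <- num_y + d * M[c, d]
    tot <- tot + M[c, d]
  }
  c(num_x / tot, num_y / tot)
}

oracle_central_moment <- function(M, i, j) {
  ctr <- oracle_centroid(M)
  s <- 0
  for (b in seq_len(nrow(M))) for (q in seq_len(ncol(M)))
    s <- s + (b - ctr[1])^i * (q - ctr[2])^j * M[b, q]
  unname(s)
}

# term-by-term Hahn polynomial with its own rising factorial
oracle_poch <- function(x, k) {
  out <- 1
  i <- 0
  while (i < k) { out <- out * (x + i); i <- i + 1 }
  out
}

oracle_hahn_poly <- function(n, r, N, u = 0, v = 0) {
  total <- 0
  for (k in 0:n) {
    term <- (-1)^k * oracle_poch(-n, k) * oracle_poch(-r, k) *
      oracle_poch(2 * N + u + v - n - 1, k) /
      (oracle_poch(N + v - 1, k) * oracle_poch(N - 1, k) * factorial(k))
    total <- total + term
  }
  oracle_poch(N + v - 1, n) * oracle_poch(N - 1, n) * total
}

oracle_hahn_moment <- function(M, i, j, u = 0, v = 0) {
  N <- nrow(M)
  s <- 0
  for (p in 0:(N - 1)) for (q in 0:(N - 1))
    s <- s + M[p + 1, q + 1] * oracle_hahn_poly(i, p, N, u, v) *
      oracle_hahn_poly(j, q, N, u, v)
  unname(s)
}

# PRIM by explicit enumeration of ordered pairs p < q
oracle_prim <- function(tokens, side) {
  V <- matrix(0, side, side)
  L <- length(tokens)
  if (L >= 2) for (p in 1:(L - 1)) for (q in (p + 1):L)
    V[tokens[p], tokens[q]] <- V[tokens[p], tokens[q]] + (q - p)
  V
}

# overlapping substring counts
oracle_kmer_count <- function(seq, kmer) {
  k <- nchar(kmer)
  hits <- 0
  for (p in seq_len(nchar(seq) - k + 1))
    if (substr(seq, p, p + k - 1) == kmer) hits <- hits + 1
  hits
}

oracle_position_sum <- function(seq, kmer) {
  k <- nchar(kmer)
  s <- 0
  for (p in seq_len(nchar(seq) - k + 1))
    if (substr(seq, p, p + k - 1) == kmer) s <- s + p
  s
}

# AUROC by O(n^2) pair counting, ties half
oracle_auroc <- function(y, s) {
  pos <- which(y == 1); neg <- which(y == 0)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + if (s[i] > s[j]) 1 else if (s[i] == s[j]) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# tiny linearly separable feature set: class decided by column 1
toy_separable <- function(n = 20L, p = 5L, seed = 42L) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  X <- matrix(rnorm(n * p), n, p)
  X[, 1] <- ifelse(y == 1, 3, -3) + rnorm(n, sd = 0.1)
  X[, 2] <- X[, 1] + rnorm(n, sd = 0.1)
  colnames(X) <- paste0("f", seq_len(p))
  list(X = X, y = y)
}
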