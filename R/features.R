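# Feature groups: PRIM / RPRIM / frequency vector / AAPIV / RAAPIV /
# sequence-matrix moments, assembled into the 522-value encoding.

#' Lexicographic k-mer alphabet
#' @param k k-mer level in 1..3.
#' @return Character vector of the 4^k k-mers, A < C < G < U.
#' @export
kmer_names <- function(k) {
  stopifnot(k %in% 1:3)
  out <- RNA_BASES
  if (k > 1L) for (i in 2:k) {
    out <- as.vector(t(outer(out, RNA_BASES, paste0)))
  }
  out
}

#' Tokenize a window into overlapping k-mer codes
#'
#' Overlapping windows of width k, stride 1; each k-mer maps to its
#' 1-based lexicographic rank (first base most significant), consistent
#' with the A=1..U=4 base codes.
#'
#' @param window An `rna_window` or character scalar.
#' @param k Level in \{1, 2, 3\}.
#' @return Integer vector of L - k + 1 codes in 1..4^k.
#' @export
tokenize <- function(window, k = 1L) {
  if (!k %in% 1:3) stop("k-mer level must be 1, 2 or 3")
  codes <- encode_bases(window)
  L <- length(codes)
  if (L < k) stop("sequence shorter than k")
  n <- L - k + 1L
  tok <- integer(n)
  for (j in seq_len(k)) {
    tok <- tok + (codes[j:(j + n - 1L)] - 1L) * 4L^(k - j)
  }
  tok + 1L
}

#' Fold a token stream into a square sequence matrix
#'
#' Row-major fill of the token codes into the smallest square that holds
#' them, zero-padded at the tail; the moment engine then reduces this
#' matrix to 30 coefficients.
#'
#' @param tokens Integer token stream from [tokenize()].
#' @return A d x d numeric matrix, d = ceiling(sqrt(length(tokens))).
#' @export
sequence_matrix <- function(tokens) {
  n <- length(tokens)
  if (n == 0L) stop("empty token stream")
  d <- ceiling(sqrt(n))
  cells <- c(as.numeric(tokens), numeric(d * d - n))
  matrix(cells, nrow = d, ncol = d, byrow = TRUE)
}

#' Position-relative incidence matrix (PRIM)
#'
#' Accumulates the relative positioning of ordered k-mer pairs: cell
#' (i, j) sums the positional gaps q - p over every ordered pair of
#' stream positions p < q with token i at p and token j at q. Streams
#' with fewer than two tokens give the zero matrix.
#'
#' @param tokens Integer token stream.
#' @param k Level the stream was tokenized at (sets the 4^k side).
#' @return A 4^k x 4^k numeric matrix.
#' @export
prim <- function(tokens, k = 1L) {
  if (!k %in% 1:3) stop("k-mer level must be 1, 2 or 3")
  side <- 4L^k
  V <- matrix(0, side, side)
  L <- length(tokens)
  if (L < 2L) return(V)
  pq <- which(upper.tri(matrix(FALSE, L, L)), arr.ind = TRUE)
  lin <- tokens[pq[, 1L]] + (tokens[pq[, 2L]] - 1L) * side
  agg <- rowsum(as.numeric(pq[, 2L] - pq[, 1L]), group = lin)
  V[as.integer(rownames(agg))] <- agg[, 1L]
  V
}

#' Reverse PRIM (RPRIM)
#'
#' PRIM of the reversed window: the symbols are reversed first, then
#' tokenized, capturing downstream-to-upstream positional structure.
#'
#' @param window An `rna_window` or character scalar.
#' @param k Level in \{1, 2, 3\}.
#' @return A 4^k x 4^k numeric matrix.
#' @export
rprim <- function(window, k = 1L) {
  prim(tokenize(reverse_window(window), k), k)
}

#' k-mer frequency vector
#'
#' Counts of every mono-, di- and tri-nucleotide from overlapping
#' tokenization: 4 + 16 + 64 = 84 nonnegative integers.
#'
#' @param window An `rna_window` or character scalar.
#' @return Named integer vector of length 84.
#' @export
frequency_vector <- function(window) {
  out <- unlist(lapply(1:3, function(k) {
    cnt <- tabulate(tokenize(window, k), nbins = 4L^k)
    names(cnt) <- kmer_names(k)
    cnt
  }))
  out
}

position_sums <- function(tokens, side) {
  v <- numeric(side)
  if (length(tokens)) {
    agg <- rowsum(as.numeric(seq_along(tokens)), group = tokens)
    v[as.integer(rownames(agg))] <- agg[, 1L]
  }
  v
}

#' Accumulative absolute position incidence vectors (AAPIV)
#'
#' For each k-mer, the sum of the 1-based start positions of its
#' occurrences in the forward token stream; one vector per level
#' (lengths 4, 16, 64).
#'
#' @param window An `rna_window` or character scalar.
#' @return Named list of numeric vectors `k1`, `k2`, `k3`.
#' @export
aapiv <- function(window) {
  out <- lapply(1:3, function(k) {
    v <- position_sums(tokenize(window, k), 4L^k)
    names(v) <- kmer_names(k)
    v
  })
  names(out) <- paste0("k", 1:3)
  out
}

#' Reverse AAPIV (RAAPIV)
#'
#' AAPIV computed on the reversed symbol sequence.
#'
#' @inheritParams aapiv
#' @return Named list of numeric vectors `k1`, `k2`, `k3`.
#' @export
raapiv <- function(window) {
  aapiv(reverse_window(window))
}

moment_block <- function(mats, u, v) {
  unlist(lapply(seq_along(mats), function(i) {
    ms <- moment_set(mats[[i]], u = u, v = v)
    names(ms) <- paste0("k", i, ".", names(ms))
    ms
  }))
}

#' Assemble the full 522-value feature vector of a window
#'
#' Frozen concatenation (group sizes in parentheses): PRIM moments (90),
#' RPRIM moments (90), frequency vector (84), AAPIV (84), RAAPIV (84),
#' sequence-matrix moments (90). Matrix-valued groups contribute their
#' 30 moment coefficients per k-level rather than raw cells.
#'
#' @param window An `rna_window` (or character scalar of a valid window).
#' @param u,v Hahn shape parameters (default 0).
#' @return Named numeric vector of length 522.
#' @export
assemble_features <- function(window, u = 0, v = 0) {
  fwd <- lapply(1:3, function(k) tokenize(window, k))
  prim_m <- moment_block(lapply(1:3, function(k) prim(fwd[[k]], k)), u, v)
  rwin <- reverse_window(window)
  rprim_m <- moment_block(
    lapply(1:3, function(k) prim(tokenize(rwin, k), k)), u, v)
  fv <- frequency_vector(window)
  ap <- unlist(lapply(seq_along(fwd), function(k) {
    v4 <- position_sums(fwd[[k]], 4L^k)
    names(v4) <- paste0("k", k, ".", kmer_names(k))
    v4
  }))
  rap_list <- raapiv(window)
  rap <- unlist(lapply(1:3, function(k) {
    v4 <- rap_list[[k]]
    names(v4) <- paste0("k", k, ".", names(v4))
    v4
  }))
  seqm <- moment_block(lapply(fwd, sequence_matrix), u, v)
  out <- c(stats::setNames(prim_m, paste0("PRIM.", names(prim_m))),
           stats::setNames(rprim_m, paste0("RPRIM.", names(rprim_m))),
           stats::setNames(as.numeric(fv), paste0("FV.", names(fv))),
           stats::setNames(ap, paste0("AAPIV.", names(ap))),
           stats::setNames(rap, paste0("RAAPIV.", names(rap))),
           stats::setNames(seqm, paste0("SEQMAT.", names(seqm))))
  out
}

#' Sizes and order of the feature groups
#' @return Named integer vector of group widths summing to 522.
#' @export
feature_groups <- function() {
  c(PRIM = 90L, RPRIM = 90L, FV = 84L, AAPIV = 84L, RAAPIV = 84L,
    SEQMAT = 90L)
}

#' Encode a set of windows as a feature matrix
#'
#' @param windows List of `rna_window` objects.
#' @param u,v Hahn shape parameters.
#' @return Numeric matrix, one row per window, 522 named columns;
#'   row names are window ids, with a `label` attribute carrying the
#'   window labels.
#' @export
feature_matrix <- function(windows, u = 0, v = 0) {
  stopifnot(length(windows) > 0L)
  rows <- lapply(windows, assemble_features, u = u, v = v)
  X <- do.call(rbind, rows)
  rownames(X) <- vapply(windows, function(w) w$id, character(1L))
  attr(X, "label") <- vapply(windows, function(w) w$label, character(1L))
  X
}
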