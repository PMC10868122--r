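#' The frozen set of moment orders
#'
#' All moment families are evaluated at the ten order pairs (j,k) with
#' j + k <= 3, in a fixed documented order, so that every matrix-valued
#' feature group contributes exactly 30 coefficients (10 raw + 10
#' central + 10 Hahn).
#'
#' @return A 10 x 2 integer matrix of (j, k) pairs.
#' @export
moment_orders <- function() {
  m <- matrix(c(0L, 0L, 0L, 1L, 1L, 0L, 1L, 1L, 0L, 2L,
                2L, 0L, 1L, 2L, 2L, 1L, 0L, 3L, 3L, 0L),
              ncol = 2L, byrow = TRUE)
  colnames(m) <- c("j", "k")
  m
}

order_labels <- function() {
  o <- moment_orders()
  paste0(o[, 1L], o[, 2L])
}

check_square <- function(M) {
  if (!is.matrix(M) || nrow(M) != ncol(M) || nrow(M) < 1L)
    stop("M must be a nonempty square matrix")
  storage.mode(M) <- "double"
  M
}

#' Centroid of a square matrix
#'
#' Mass-weighted mean row and column index (1-based), the centre about
#' which central moments are taken.
#'
#' @param M Square numeric matrix with nonzero total mass.
#' @return Numeric vector `c(xbar, ybar)`.
#' @export
matrix_centroid <- function(M) {
  M <- check_square(M)
  tot <- sum(M)
  if (tot == 0) stop("degenerate matrix: total mass is zero")
  idx <- seq_len(nrow(M))
  c(xbar = sum(idx * rowSums(M)) / tot,
    ybar = sum(idx * colSums(M)) / tot)
}

#' Raw moments of a square matrix
#'
#' N_jk = sum_c sum_d c^j d^k M[c,d] over 1-based indices, for each
#' order pair in [moment_orders()].
#'
#' @param M Square numeric matrix.
#' @return Named numeric vector of 10 raw moments.
#' @export
raw_moments <- function(M) {
  M <- check_square(M)
  idx <- seq_len(nrow(M))
  o <- moment_orders()
  out <- vapply(seq_len(nrow(o)), function(i) {
    as.numeric(idx^o[i, 1L] %*% M %*% idx^o[i, 2L])
  }, numeric(1L))
  names(out) <- paste0("raw", order_labels())
  out
}

#' Central moments of a square matrix
#'
#' Raw-moment sums with indices taken about the matrix centroid, so the
#' coefficients reflect composition and shape rather than location.
#'
#' @inheritParams raw_moments
#' @return Named numeric vector of 10 central moments.
#' @export
central_moments <- function(M) {
  M <- check_square(M)
  ctr <- matrix_centroid(M)
  idx <- seq_len(nrow(M))
  dx <- idx - ctr[["xbar"]]
  dy <- idx - ctr[["ybar"]]
  o <- moment_orders()
  out <- vapply(seq_len(nrow(o)), function(i) {
    as.numeric(dx^o[i, 1L] %*% M %*% dy^o[i, 2L])
  }, numeric(1L))
  names(out) <- paste0("central", order_labels())
  out
}

#' Rising-factorial Pochhammer symbol (x)_k = x (x+1) ... (x+k-1)
#' @param x Numeric base.
#' @param k Nonnegative integer.
#' @return The rising factorial; 1 when k = 0.
#' @export
pochhammer <- function(x, k) {
  if (k == 0L) return(1)
  prod(x + seq_len(k) - 1)
}

#' Discrete Hahn polynomial value
#'
#' Evaluates h_n^{u,v}(r, N) =
#' (N+v-1)_n (N-1)_n * sum_{k=0}^{n} (-1)^k
#'   (-n)_k (-r)_k (2N+u+v-n-1)_k / ((N+v-1)_k (N-1)_k k!),
#' with rising-factorial Pochhammer symbols; u and v are shape
#' parameters of the polynomial family.
#'
#' @param n Polynomial order (nonnegative integer).
#' @param r Abscissa, usually 0 <= r < N.
#' @param N Support size.
#' @param u,v Shape parameters (default 0).
#' @return Polynomial value (numeric scalar).
#' @export
hahn_poly <- function(n, r, N, u = 0, v = 0) {
  if (n < 0) stop("order n must be nonnegative")
  pref <- pochhammer(N + v - 1, n) * pochhammer(N - 1, n)
  acc <- 0
  for (k in 0:n) {
    den <- pochhammer(N + v - 1, k) * pochhammer(N - 1, k) * factorial(k)
    if (den == 0) stop("Hahn polynomial denominator vanished (k=", k, ")")
    num <- pochhammer(-n, k) * pochhammer(-r, k) *
      pochhammer(2 * N + u + v - n - 1, k)
    acc <- acc + (-1)^k * num / den
  }
  pref * acc
}

# table of h_n(r) for n = 0..max_n, r = 0..N-1 (rows r, cols n)
hahn_table <- function(N, max_n, u, v) {
  outer(0:(N - 1L), 0:max_n,
        Vectorize(function(r, n) hahn_poly(n, r, N, u, v)))
}

#' Hahn moments of a square matrix
#'
#' Projects the matrix onto products of discrete Hahn polynomials, one
#' polynomial per axis: H_ij = sum_pq M[p+1, q+1] h_i(p, N) h_j(q, N)
#' with 0-based p, q.
#'
#' @inheritParams raw_moments
#' @param u,v Hahn shape parameters (default 0).
#' @return Named numeric vector of 10 Hahn moments at the frozen orders.
#' @export
hahn_moments <- function(M, u = 0, v = 0) {
  M <- check_square(M)
  N <- nrow(M)
  o <- moment_orders()
  max_n <- max(o)
  H <- hahn_table(N, max_n, u, v)          # N x (max_n+1)
  proj <- crossprod(H, M %*% H)            # (max_n+1) square, proj[i+1, j+1]
  out <- vapply(seq_len(nrow(o)), function(i) {
    proj[o[i, 1L] + 1L, o[i, 2L] + 1L]
  }, numeric(1L))
  names(out) <- paste0("hahn", order_labels())
  out
}

#' Full 30-coefficient moment set of a square matrix
#'
#' The frozen concatenation raw(10) + central(10) + Hahn(10) used for
#' every matrix-valued feature group.
#'
#' @inheritParams hahn_moments
#' @return Named numeric vector of length 30.
#' @export
moment_set <- function(M, u = 0, v = 0) {
  c(raw_moments(M), central_moments(M), hahn_moments(M, u = u, v = v))
}
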