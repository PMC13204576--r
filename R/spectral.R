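#' Degree matrix of a weighted graph
#'
#' @param A square nonnegative adjacency/weight matrix.
#' @return diagonal matrix with `D[i,i] = sum_j A[i,j]`.
#' @export
degree_matrix <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) stop_input("A must be a square matrix")
  if (any(A < 0)) stop_input("A must be nonnegative")
  diag(rowSums(A), nrow(A))
}

#' Combinatorial graph Laplacian
#'
#' `L = D - A`. Rows sum to zero and `L` is positive semidefinite for any
#' symmetric nonnegative `A`.
#'
#' @param A symmetric nonnegative adjacency matrix with zero diagonal.
#' @return the Laplacian matrix.
#' @export
laplacian <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) stop_input("A must be a square matrix")
  if (max(abs(A - t(A))) > 1e-12) stop_input("A must be symmetric")
  if (any(A < 0)) stop_input("A must be nonnegative")
  degree_matrix(A) - A
}

#' Largest eigenvalue by power iteration
#'
#' Plain power iteration on a symmetric positive semidefinite matrix with a
#' fixed deterministic start vector; the Rayleigh quotient is returned when
#' successive estimates agree to `tol` (relative).
#'
#' @param M symmetric PSD matrix.
#' @param tol relative convergence tolerance.
#' @param max_iter iteration cap.
#' @return the dominant eigenvalue estimate.
#' @export
lambda_max_power <- function(M, tol = 1e-13, max_iter = 5000L) {
  n <- nrow(M)
  v <- cos(seq_len(n) * 1.2345) + 0.1  # deterministic, generically non-orthogonal
  v <- v / sqrt(sum(v^2))
  lam <- 0
  for (i in seq_len(max_iter)) {
    w <- M %*% v
    nw <- sqrt(sum(w^2))
    if (nw < 1e-300) return(0)         # M (numerically) zero on this vector
    v <- as.vector(w) / nw
    lam_new <- sum(v * (M %*% v))
    if (abs(lam_new - lam) <= tol * max(abs(lam_new), 1)) return(lam_new)
    lam <- lam_new
  }
  lam
}

#' Rescaled graph Laplacian with spectrum in \[-1, 1\]
#'
#' Chebyshev polynomial filters require an operator whose spectrum lies in
#' `[-1, 1]`. With `normalization = "sym"` the symmetric-normalized
#' Laplacian `L_n = D^{-1/2} (D - A) D^{-1/2}` (spectrum in `[0, 2]`) is
#' used; with `"comb"` the combinatorial `L = D - A`. Either is then mapped
#' to `Lt = 2 L_n / lambda_max - I`. Isolated nodes are handled by
#' substituting unit degree in the normalizing scale only, so an edgeless
#' graph has `L_n = 0` and, by convention (`lambda_max ~ 0` guard),
#' `Lt = -I`.
#'
#' @param A symmetric nonnegative adjacency matrix, zero diagonal.
#' @param normalization `"sym"` (default) or `"comb"`.
#' @param lambda_max optional known spectral bound; computed by
#'   [lambda_max_power()] when `NULL`.
#' @return list with `Lt` (the rescaled operator), `lambda_max` and
#'   `normalization`.
#' @export
scaled_laplacian <- function(A, normalization = c("sym", "comb"), lambda_max = NULL) {
  normalization <- match.arg(normalization)
  L <- laplacian(A)
  if (normalization == "sym") {
    d <- rowSums(A)
    d[d == 0] <- 1                      # unit-degree substitution for isolated nodes
    s <- 1 / sqrt(d)
    Ln <- L * outer(s, s)
  } else {
    Ln <- L
  }
  if (is.null(lambda_max)) {
    lambda_max <- lambda_max_power(Ln)
    lambda_max <- lambda_max * (1 + 1e-7)  # guard against slight underestimation
  }
  n <- nrow(A)
  Lt <- if (lambda_max < 1e-12) {
    diag(-1, n)                         # edgeless-graph convention
  } else {
    2 * Ln / lambda_max - diag(1, n)
  }
  list(Lt = Lt, lambda_max = lambda_max, normalization = normalization)
}

#' Apply the Chebyshev polynomial basis to a signal
#'
#' Computes `[T_0(Lt) x, T_1(Lt) x, ..., T_{order-1}(Lt) x]` with the
#' recurrence `T_k = 2 Lt T_{k-1} - T_{k-2}`, `T_0 x = x`, `T_1 x = Lt x`.
#' Only matrix-vector (or matrix-matrix) products with `Lt` are formed;
#' powers of `Lt` are never materialized.
#'
#' @param Lt rescaled Laplacian (e.g. from [scaled_laplacian()]).
#' @param x numeric vector or `n x f` matrix signal.
#' @param order number of basis terms, `>= 1`.
#' @return list of length `order` with the filtered signals.
#' @export
cheb_basis_apply <- function(Lt, x, order) {
  if (order < 1) stop_input("order must be >= 1")
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  out <- vector("list", order)
  out[[1]] <- x
  if (order >= 2) out[[2]] <- Lt %*% x
  if (order >= 3) {
    for (k in 3:order) out[[k]] <- 2 * (Lt %*% out[[k - 1]]) - out[[k - 2]]
  }
  out
}
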