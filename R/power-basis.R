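#' Normalized matrix-power basis of a structural matrix
#'
#' Computes `S^0, S^1, ..., S^k_max` by iterated multiplication and divides
#' each power by its own maximum absolute entry `m_k = max(|S^k|)` so the
#' design stays well scaled: without this, powers of large matrices overflow
#' rapidly. The scale factors are kept so fitted coefficients can be restored
#' to the original power scale (`c_k / m_k`). An all-zero power gets
#' `m_k = 1` by convention.
#'
#' The k-th power of the adjacency matrix counts (or, for weighted graphs,
#' weights) walks of length k between node pairs, so the basis spans direct
#' (k = 1) and indirect (k >= 2) structural pathways; k = 0 is the identity,
#' an offset for within-node self-coupling.
#'
#' @param s a structural [connectivity_matrix()].
#' @param k_max maximum path length; must satisfy `0 <= k_max <= N - 1`
#'   (a polynomial in an N x N matrix needs degree at most N - 1).
#' @return an object of class `power_basis`: a list with
#'   `normalized_powers` (list of K+1 matrices, max-abs entry 1),
#'   `scale_factors` (numeric, `m_k`), and `k_max`.
#' @examples
#' s <- connectivity_matrix(matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3))
#' b <- build_power_basis(s, 2)
#' b$scale_factors
#' @export
build_power_basis <- function(s, k_max) {
  stopifnot(is_connectivity_matrix(s))
  k_max <- check_count(k_max, "k_max")
  n <- nrow(s)
  if (k_max > n - 1L) {
    stop_parameter(sprintf(
      "k_max must be at most N - 1 = %d (Cayley-Hamilton bound); got %d.",
      n - 1L, k_max
    ))
  }
  sv <- unname(as_bare_matrix(s))
  raw <- vector("list", k_max + 1L)
  raw[[1L]] <- diag(n)
  if (k_max >= 1L) {
    for (k in seq_len(k_max)) raw[[k + 1L]] <- raw[[k]] %*% sv
  }
  scale_factors <- vapply(raw, function(p) {
    m <- max(abs(p))
    if (m == 0) 1 else m
  }, numeric(1L))
  normalized <- Map(function(p, m) p / m, raw, scale_factors)
  structure(
    list(
      normalized_powers = normalized,
      scale_factors = scale_factors,
      k_max = k_max
    ),
    class = "power_basis"
  )
}

#' Vectorize the lower triangle (diagonal included) of a symmetric matrix
#'
#' All matrices in the mapping are symmetric, so only the diagonal plus the
#' strict lower triangle carry information: each unordered node pair
#' contributes exactly once, avoiding double-weighting of off-diagonal
#' entries in the least-squares fit. Ordering is column-major over pairs
#' (i, j) with i >= j, which is R's native `lower.tri` order.
#'
#' @param m symmetric numeric matrix.
#' @param tol absolute symmetry tolerance.
#' @return numeric vector of length `N(N+1)/2`.
#' @seealso [unvectorize_lower()] for the inverse.
#' @export
vectorize_lower <- function(m, tol = 1e-9) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop_validation("input must be a square matrix.")
  }
  if (max(abs(m - t(m))) > tol) {
    stop_validation("input matrix is not symmetric.")
  }
  m[lower.tri(m, diag = TRUE)]
}

#' @rdname vectorize_lower
#' @param v vector of length `N(N+1)/2` as produced by `vectorize_lower()`.
#' @param n number of nodes N.
#' @export
unvectorize_lower <- function(v, n) {
  if (length(v) != n * (n + 1L) / 2L) {
    stop_parameter(sprintf(
      "vector length %d does not match N(N+1)/2 = %d for N = %d.",
      length(v), n * (n + 1L) / 2L, n
    ))
  }
  m <- matrix(0, n, n)
  m[lower.tri(m, diag = TRUE)] <- v
  m <- m + t(m)
  diag(m) <- diag(m) / 2
  m
}

#' Assemble the regression design matrix from a power basis
#'
#' Column 1 is all ones — the vectorized constant matrix carrying the global
#' shared input G. Columns 2 to K+2 are the vectorized normalized powers
#' `S^0/m_0, ..., S^K/m_K` in order.
#'
#' @param basis a [build_power_basis()] result.
#' @return numeric matrix of shape `N(N+1)/2` by `K+2`.
#' @export
assemble_design <- function(basis) {
  stopifnot(inherits(basis, "power_basis"))
  cols <- vapply(
    basis$normalized_powers, vectorize_lower,
    numeric(nrow(basis$normalized_powers[[1L]]) *
              (nrow(basis$normalized_powers[[1L]]) + 1L) / 2L)
  )
  unname(cbind(1, cols))
}
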