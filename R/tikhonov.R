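#' Tikhonov-regularized least squares with a per-column penalty mask
#'
#' Minimizes `||y - X b||^2 + mu * ||b[penalized]||^2`. Only the columns
#' flagged in `penalized` are shrunk; the global-input column is left free so
#' the penalty matches the objective `mu * ||c||^2` over the path-length
#' coefficients alone. Solved through the SVD of the augmented system
#' (`sqrt(mu)` identity rows appended for penalized columns), never by
#' forming normal equations, so ill-conditioned designs are handled stably.
#'
#' @param x design matrix (rows = observations).
#' @param y response vector, `length(y) == nrow(x)`.
#' @param mu nonnegative ridge weight.
#' @param penalized logical mask, one entry per column of `x`; `TRUE` means
#'   the coefficient is shrunk. Defaults to all columns.
#' @return numeric coefficient vector, one entry per column.
#' @examples
#' # ridge on an identity design has the closed form y / (1 + mu)
#' solve_tikhonov(diag(3), c(1, 2, 3), mu = 1)
#' @export
solve_tikhonov <- function(x, y, mu, penalized = rep(TRUE, ncol(x))) {
  x <- as.matrix(x)
  if (nrow(x) != length(y)) {
    stop_validation(sprintf(
      "design has %d rows but response has length %d.", nrow(x), length(y)
    ))
  }
  if (length(penalized) != ncol(x)) {
    stop_validation("`penalized` mask must have one entry per design column.")
  }
  if (length(mu) != 1L || !is.finite(mu) || mu < 0) {
    stop_parameter("`mu` must be a single finite value >= 0.")
  }
  if (mu == 0) {
    zero_col <- which(colSums(abs(x)) == 0)
    if (length(zero_col) > 0L) {
      stop_parameter(sprintf(
        "design column %d is identically zero and mu = 0 leaves the problem rank-deficient; use mu > 0.",
        zero_col[1L]
      ))
    }
  }
  x_aug <- x
  y_aug <- y
  if (mu > 0 && any(penalized)) {
    pen_rows <- diag(ncol(x))[penalized, , drop = FALSE] * sqrt(mu)
    x_aug <- rbind(x, pen_rows)
    y_aug <- c(y, rep(0, sum(penalized)))
  }
  sv <- svd(x_aug)
  tol <- max(dim(x_aug)) * max(sv$d) * .Machine$double.eps
  keep <- sv$d > tol
  drop(sv$v[, keep, drop = FALSE] %*%
         ((crossprod(sv$u[, keep, drop = FALSE], y_aug)) / sv$d[keep]))
}

#' Select the ridge weight by generalized cross-validation
#'
#' Evaluates `GCV(mu) = n * ||(I - H(mu)) y||^2 / trace(I - H(mu))^2` over a
#' grid, where `H(mu)` is the hat matrix of [solve_tikhonov()] (penalized
#' columns contribute `mu` to the penalty block; unpenalized columns do
#' not). GCV approximates leave-one-out error without refitting per fold and
#' is rotation invariant. Ties on the grid are broken toward the larger
#' `mu`, the more conservative (more regularized) choice.
#'
#' @inheritParams solve_tikhonov
#' @param mu_grid strictly positive, ascending candidate values.
#' @return a list: `mu_star` (grid minimizer), `gcv_curve` (tibble with
#'   columns `mu`, `gcv`).
#' @export
gcv_select <- function(x, y, mu_grid = default_mu_grid(),
                       penalized = rep(TRUE, ncol(x))) {
  x <- as.matrix(x)
  if (length(mu_grid) == 0L) stop_parameter("`mu_grid` must be nonempty.")
  if (any(mu_grid <= 0)) {
    stop_parameter("all `mu_grid` values must be strictly positive.")
  }
  if (is.unsorted(mu_grid, strictly = TRUE)) {
    stop_parameter("`mu_grid` must be sorted strictly ascending.")
  }
  n <- nrow(x)
  xtx <- crossprod(x)
  pen_diag <- diag(as.numeric(penalized), ncol(x))
  gcv <- vapply(mu_grid, function(mu) {
    b <- solve_tikhonov(x, y, mu, penalized)
    rss <- sum((y - x %*% b)^2)
    tr_h <- sum(diag(pinv_solve(xtx + mu * pen_diag, xtx)))
    n * rss / (n - tr_h)^2
  }, numeric(1L))
  best <- max(which(gcv <= min(gcv) * (1 + 1e-10)))
  list(
    mu_star = mu_grid[best],
    gcv_curve = tibble::tibble(mu = mu_grid, gcv = gcv)
  )
}

#' @rdname gcv_select
#' @param lower,upper,length.out bounds and size of the default log-spaced
#'   grid. The defaults span effectively-unregularized (1e-8) to
#'   heavily-shrunk (1e2) for max-abs-normalized designs.
#' @export
default_mu_grid <- function(lower = 1e-8, upper = 1e2, length.out = 30L) {
  10^seq(log10(lower), log10(upper), length.out = length.out)
}

# SVD-based solve of A X = B tolerating singular A (min-norm solution)
pinv_solve <- function(a, b) {
  sv <- svd(a)
  tol <- max(dim(a)) * max(sv$d) * .Machine$double.eps
  keep <- sv$d > tol
  sv$v[, keep, drop = FALSE] %*%
    (crossprod(sv$u[, keep, drop = FALSE], b) / sv$d[keep])
}
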