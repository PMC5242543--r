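#' Convert a correlation-type connectivity matrix to a dissimilarity matrix
#'
#' Applies `D = 1 - |F|` elementwise: strongly (anti)correlated node pairs
#' become close, uncorrelated pairs distant. Entries must lie in \[-1, 1\];
#' when any entry exceeds 1 in magnitude (e.g. a model prediction, which is
#' not itself a correlation matrix) the whole matrix is first rescaled by
#' its maximum absolute value, with a warning unless `quiet = TRUE`. The
#' diagonal is forced to 0.
#'
#' @param f a [connectivity_matrix()] or symmetric numeric matrix.
#' @param quiet suppress the rescaling warning.
#' @return symmetric dissimilarity matrix with entries in \[0, 1\] and zero
#'   diagonal.
#' @export
dissimilarity_from_connectivity <- function(f, quiet = FALSE) {
  vals <- as_bare_matrix(if (is_connectivity_matrix(f)) f else as.matrix(f))
  mx <- max(abs(vals))
  if (mx > 1) {
    if (!quiet) {
      warning(sprintf(
        "entries outside [-1, 1] (max |entry| = %.3g); rescaling by the maximum absolute value before 1 - |corr| conversion.",
        mx
      ), call. = FALSE)
    }
    vals <- vals / mx
  }
  d <- 1 - abs(vals)
  d <- pmin(pmax(d, 0), 1)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d
}

#' Zeroth-Betti-number barcode of a dissimilarity filtration
#'
#' Sweeps a threshold `lambda` over the dissimilarity matrix: two nodes are
#' joined by an edge when their distance is strictly less than `lambda`.
#' `beta0(lambda)` is the number of connected components of that graph — N
#' at `lambda = 0` (no edges yet), nonincreasing as `lambda` grows. The
#' barcode records the merge heights exactly via a sorted-edge union-find
#' (Kruskal order): the breakpoints are the distinct single-linkage merge
#' heights, i.e. the edge weights of a minimum spanning forest. The step
#' function is left-continuous: at `lambda` equal to a merge height the
#' merge has NOT yet happened (strict `d < lambda`).
#'
#' @param d symmetric nonnegative dissimilarity matrix with zero diagonal,
#'   e.g. from [dissimilarity_from_connectivity()].
#' @return an object of class `betti_barcode`: `breakpoints` (strictly
#'   increasing merge heights), `counts` (component counts, starting at N,
#'   one entry more than `breakpoints`), `n_nodes`.
#' @examples
#' d <- matrix(0, 3, 3)
#' d[1, 2] <- d[2, 1] <- 0.2
#' d[2, 3] <- d[3, 2] <- 0.5
#' d[1, 3] <- d[3, 1] <- 0.9
#' b <- betti0_barcode(d)
#' b$breakpoints # 0.2, 0.5
#' evaluate_barcode(b, 0.2) # still 3: strict inequality
#' @export
betti0_barcode <- function(d) {
  d <- if (is_connectivity_matrix(d)) as_bare_matrix(d) else as.matrix(d)
  if (nrow(d) != ncol(d)) stop_validation("dissimilarity matrix must be square.")
  if (max(abs(d - t(d))) > 1e-9) {
    stop_validation("dissimilarity matrix must be symmetric.")
  }
  if (any(d < 0)) stop_validation("dissimilarity entries must be nonnegative.")
  n <- nrow(d)
  if (n == 0L) stop_validation("empty matrix.")

  iu <- which(upper.tri(d))
  w <- d[iu]
  ord <- order(w)
  ii <- ((iu - 1L) %% n) + 1L  # row index of upper-tri entries
  jj <- ((iu - 1L) %/% n) + 1L # col index
  ii <- ii[ord]
  jj <- jj[ord]
  w <- w[ord]

  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  merge_heights <- numeric(0)
  comps <- n
  for (e in seq_along(w)) {
    if (comps == 1L) break
    ra <- find(ii[e])
    rb <- find(jj[e])
    if (ra != rb) {
      parent[ra] <- rb
      comps <- comps - 1L
      merge_heights <- c(merge_heights, w[e])
    }
  }
  breakpoints <- unique(merge_heights) # sorted: edges processed in order
  counts <- as.integer(
    c(n, n - cumsum(tabulate(match(merge_heights, breakpoints))))
  )
  structure(
    list(breakpoints = breakpoints, counts = counts, n_nodes = n),
    class = "betti_barcode"
  )
}

#' @export
print.betti_barcode <- function(x, ...) {
  cat(sprintf(
    "<betti_barcode> N = %d; %d merge heights; final component count %d\n",
    x$n_nodes, length(x$breakpoints), x$counts[length(x$counts)]
  ))
  invisible(x)
}

#' Evaluate a barcode step function at a filtration value
#'
#' Uses the left-continuity convention of [betti0_barcode()]: at `lambda`
#' equal to a merge height the components are still unmerged.
#'
#' @param b a `betti_barcode`.
#' @param lam nonnegative filtration value (vectorized).
#' @return integer component count(s).
#' @export
evaluate_barcode <- function(b, lam) {
  stopifnot(inherits(b, "betti_barcode"))
  if (any(lam < 0)) stop_parameter("`lam` must be nonnegative.")
  idx <- vapply(lam, function(l) sum(b$breakpoints < l), integer(1L))
  b$counts[idx + 1L]
}

#' Barcode-based network dissimilarity SSE_beta
#'
#' The squared difference of two beta0 step functions integrated exactly
#' over the filtration range \[0, 1\] and divided by N^2, which makes the
#' measure independent of network size. The integral is computed by merging
#' the two breakpoint lists and summing piecewise-constant contributions —
#' no numerical quadrature, so there is no resolution knob. Zero iff the
#' barcodes coincide; bounded above by `(N-1)^2 / N^2`.
#'
#' @param a,b `betti_barcode` objects over the same number of nodes.
#' @return a nonnegative scalar.
#' @export
sse_beta <- function(a, b) {
  stopifnot(inherits(a, "betti_barcode"), inherits(b, "betti_barcode"))
  if (a$n_nodes != b$n_nodes) {
    stop_validation(
      "barcodes over different node counts are not comparable (the N^2 normalization assumes matching N)."
    )
  }
  grid <- sort(unique(c(
    0, 1,
    a$breakpoints[a$breakpoints > 0 & a$breakpoints < 1],
    b$breakpoints[b$breakpoints > 0 & b$breakpoints < 1]
  )))
  lo <- grid[-length(grid)]
  hi <- grid[-1L]
  mid <- (lo + hi) / 2
  diff2 <- (evaluate_barcode(a, mid) - evaluate_barcode(b, mid))^2
  sum((hi - lo) * diff2) / a$n_nodes^2
}

#' Export a barcode as two-column text
#'
#' Header line records N; body has one `breakpoint<TAB>count` row per merge
#' height, where `count` is the component count attained just above the
#' breakpoint.
#'
#' @param b a `betti_barcode`.
#' @param path output path.
#' @export
write_barcode <- function(b, path) {
  stopifnot(inherits(b, "betti_barcode"))
  lines <- c(
    sprintf("# n_nodes\t%d", b$n_nodes),
    "breakpoint\tcount",
    sprintf("%.17g\t%d", b$breakpoints, b$counts[-1L])
  )
  writeLines(lines, path)
  invisible(path)
}
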