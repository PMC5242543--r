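#' Degree-preserving rewiring null model (double-edge swaps)
#'
#' Randomizes a binary structural graph while keeping every node's degree
#' exactly fixed: repeatedly pick two edges (a,b) and (c,d) with four
#' distinct endpoints and replace them with (a,d) and (c,b), rejecting any
#' swap that would create a self-loop or a duplicate edge (the
#' Maslov-Sneppen procedure). The target number of accepted swaps is
#' `round(swaps_per_edge * edge_count)`; the attempt budget is 100x that,
#' after which the function returns the partially rewired graph with a
#' warning. Deterministic given `seed`.
#'
#' @param s binary symmetric [connectivity_matrix()] with zero diagonal
#'   (use [binarize()] first for weighted input).
#' @param swaps_per_edge accepted swaps per edge; default 10.
#' @param seed integer seed (required: the procedure is stochastic).
#' @return a list with `matrix` (the rewired `connectivity_matrix`) and
#'   `report` (class `rewire_report`): `n_swaps_performed`, `n_attempts`,
#'   `edge_overlap_fraction` (original edges still present), `seed`,
#'   `completed`, `disconnected`.
#' @export
rewire_degree_preserving <- function(s, swaps_per_edge = 10, seed) {
  stopifnot(is_connectivity_matrix(s))
  if (attr(s, "weighted")) {
    stop_validation("rewiring requires a binary matrix; apply binarize() first.")
  }
  vals <- as_bare_matrix(s)
  if (any(diag(vals) != 0)) {
    stop_validation("rewiring requires a zero diagonal (no self-loops).")
  }
  seed <- check_count(seed, "seed")
  if (swaps_per_edge <= 0) {
    stop_parameter("`swaps_per_edge` must be positive.")
  }
  idx <- which(upper.tri(vals) & vals != 0)
  n <- nrow(vals)
  n_edges <- length(idx)
  if (n_edges < 2L) {
    warning("fewer than 2 edges; returning the input unchanged.",
            call. = FALSE)
    report <- new_rewire_report(0L, 0L, 1, seed, TRUE, vals)
    return(list(matrix = s, report = report))
  }
  ei <- ((idx - 1L) %% n) + 1L
  ej <- ((idx - 1L) %/% n) + 1L
  target <- max(1L, as.integer(round(swaps_per_edge * n_edges)))
  budget <- 100L * target

  adj <- vals != 0
  accepted <- 0L
  attempts <- 0L
  with_seed(seed, {
    while (accepted < target && attempts < budget) {
      attempts <- attempts + 1L
      pick <- sample.int(n_edges, 2L)
      a <- ei[pick[1L]]; b <- ej[pick[1L]]
      c_ <- ei[pick[2L]]; d_ <- ej[pick[2L]]
      if (stats::runif(1L) < 0.5) { tmp <- c_; c_ <- d_; d_ <- tmp }
      # propose (a,d) and (c,b)
      if (length(unique(c(a, b, c_, d_))) != 4L) next
      if (adj[a, d_] || adj[c_, b]) next
      adj[a, b] <- adj[b, a] <- FALSE
      adj[c_, d_] <- adj[d_, c_] <- FALSE
      adj[a, d_] <- adj[d_, a] <- TRUE
      adj[c_, b] <- adj[b, c_] <- TRUE
      ei[pick[1L]] <- min(a, d_); ej[pick[1L]] <- max(a, d_)
      ei[pick[2L]] <- min(c_, b); ej[pick[2L]] <- max(c_, b)
      accepted <- accepted + 1L
    }
  })
  if (accepted < target) {
    warning(sprintf(
      "attempt budget exhausted: %d of %d target swaps performed.",
      accepted, target
    ), call. = FALSE)
  }
  new_vals <- adj * 1
  out <- connectivity_matrix(new_vals, labels = node_labels(s),
                             kind = attr(s, "kind"), weighted = FALSE)
  overlap <- sum(vals[upper.tri(vals)] != 0 & new_vals[upper.tri(new_vals)] != 0) /
    n_edges
  report <- new_rewire_report(accepted, attempts, overlap, seed,
                              accepted >= target, new_vals)
  list(matrix = out, report = report)
}

new_rewire_report <- function(swaps, attempts, overlap, seed, completed,
                              vals) {
  g <- igraph::graph_from_adjacency_matrix((vals != 0) * 1,
                                           mode = "undirected")
  structure(
    list(
      n_swaps_performed = swaps,
      n_attempts = attempts,
      edge_overlap_fraction = overlap,
      seed = seed,
      completed = completed,
      disconnected = igraph::components(g)$no > 1L
    ),
    class = "rewire_report"
  )
}

#' @export
print.rewire_report <- function(x, ...) {
  cat(sprintf(
    "<rewire_report> %d swaps in %d attempts; edge overlap %.1f%%; seed %d%s%s\n",
    x$n_swaps_performed, x$n_attempts, 100 * x$edge_overlap_fraction,
    x$seed,
    if (x$completed) "" else " [INCOMPLETE]",
    if (x$disconnected) " [disconnected]" else ""
  ))
  invisible(x)
}

#' Gaussian rank resampling of edge weights
#'
#' Replaces a set of (typically heavy-tailed) positive weights with the
#' same number of Gaussian draws, rank-matched: the i-th smallest draw goes
#' to the position of the i-th smallest weight (ties broken by stable
#' original order). The output therefore has exactly the weak ordering of
#' the input but a compressed dynamic range. Defaults follow the
#' Normal(0.5, 0.1) convention for fiber-strength resampling; draws are not
#' clipped at 0 or 1 (negative values are astronomically rare at these
#' parameters).
#'
#' @param weights nonempty numeric vector.
#' @param mean,sd Gaussian parameters; `sd` must be positive.
#' @param seed integer seed; deterministic given the seed.
#' @return numeric vector, same length and rank order as `weights`.
#' @export
gaussian_rank_resample <- function(weights, mean = 0.5, sd = 0.1, seed) {
  if (length(weights) == 0L) stop_parameter("`weights` must be nonempty.")
  if (length(sd) != 1L || sd <= 0) stop_parameter("`sd` must be positive.")
  seed <- check_count(seed, "seed")
  draws <- with_seed(seed, sort(stats::rnorm(length(weights), mean, sd)))
  out <- numeric(length(weights))
  out[order(weights)] <- draws # order() is stable on ties
  out
}

#' Rank-resample the weights of a structural matrix
#'
#' Applies [gaussian_rank_resample()] to the nonzero strict-lower-triangle
#' weights only, mirrors the result to the upper triangle, and leaves
#' absent edges (zeros) untouched — the sparsity pattern and the weight
#' ordering are preserved exactly while the dynamic range is compressed.
#'
#' @param s weighted symmetric [connectivity_matrix()].
#' @inheritParams gaussian_rank_resample
#' @return a weighted `connectivity_matrix` with the same zero pattern.
#' @export
resample_matrix <- function(s, mean = 0.5, sd = 0.1, seed) {
  stopifnot(is_connectivity_matrix(s))
  if (!attr(s, "weighted")) {
    warning(
      "input is binary: rank resampling a binary matrix assigns draws to tied ranks in storage order.",
      call. = FALSE
    )
  }
  vals <- as_bare_matrix(s)
  lower <- which(lower.tri(vals) & vals != 0)
  if (length(lower) == 0L) stop_validation("matrix has no edges to resample.")
  new_vals <- matrix(0, nrow(vals), ncol(vals))
  new_vals[lower] <- gaussian_rank_resample(vals[lower], mean, sd, seed)
  new_vals <- new_vals + t(new_vals)
  diag(new_vals) <- diag(vals)
  connectivity_matrix(new_vals, labels = node_labels(s),
                      kind = attr(s, "kind"), weighted = TRUE)
}
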