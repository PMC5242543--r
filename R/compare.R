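#' Direct matrix comparison measures
#'
#' `frobenius_sse()` is the squared Frobenius norm of the entrywise
#' difference — the conventional sum of squared errors between two
#' connectivity matrices. `pearson_similarity()` is the Pearson correlation
#' over the vectorized strict lower triangles (the diagonal is excluded so
#' the trivially matched unit diagonal of correlation matrices cannot
#' inflate r).
#'
#' @param f,fhat matrices of identical size ([connectivity_matrix()] or
#'   plain).
#' @return a scalar: nonnegative for `frobenius_sse()`, in \[-1, 1\] for
#'   `pearson_similarity()`.
#' @export
frobenius_sse <- function(f, fhat) {
  a <- if (is_connectivity_matrix(f)) as_bare_matrix(f) else as.matrix(f)
  b <- if (is_connectivity_matrix(fhat)) as_bare_matrix(fhat) else as.matrix(fhat)
  if (!identical(dim(a), dim(b))) {
    stop_validation("matrices must have identical dimensions.")
  }
  sum((a - b)^2)
}

#' @rdname frobenius_sse
#' @export
pearson_similarity <- function(f, fhat) {
  a <- if (is_connectivity_matrix(f)) as_bare_matrix(f) else as.matrix(f)
  b <- if (is_connectivity_matrix(fhat)) as_bare_matrix(fhat) else as.matrix(fhat)
  if (!identical(dim(a), dim(b))) {
    stop_validation("matrices must have identical dimensions.")
  }
  va <- a[lower.tri(a)]
  vb <- b[lower.tri(b)]
  if (length(va) < 3L) {
    stop_validation("need at least 3 node pairs for a correlation.")
  }
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    stop_validation("correlation undefined: one input has zero variance over node pairs.")
  }
  stats::cor(va, vb)
}

#' Automatic elbow selection on a diagnostics curve
#'
#' Finds where a goodness-of-fit curve "stops descending precipitously":
#' the smallest index K whose next step changes the curve by less than
#' `rel_tol` in relative terms — beyond that K, longer paths add little.
#' For increasing curves (e.g. Pearson r over K) the rule is sign-flipped.
#' When every step exceeds `rel_tol`, the last index is returned with
#' attribute `converged = FALSE`.
#'
#' @param curve numeric vector indexed by K.
#' @param rel_tol relative-change threshold in (0, 1); default 0.05.
#' @param direction `"auto"` (infer from endpoints), `"decreasing"`, or
#'   `"increasing"`.
#' @param eps floor for the relative-change denominator.
#' @return integer index into `curve`, with logical attribute `converged`.
#' @examples
#' select_elbow(c(10, 4, 2, 1.9, 1.89)) # 4: the step 1.9 -> 1.89 is < 5%
#' @export
select_elbow <- function(curve, rel_tol = 0.05,
                         direction = c("auto", "decreasing", "increasing"),
                         eps = 1e-12) {
  direction <- match.arg(direction)
  if (length(curve) == 0L) stop_parameter("`curve` must be nonempty.")
  if (length(rel_tol) != 1L || rel_tol <= 0 || rel_tol >= 1) {
    stop_parameter("`rel_tol` must lie in (0, 1).")
  }
  if (length(curve) == 1L) {
    return(structure(1L, converged = TRUE))
  }
  if (direction == "auto") {
    direction <- if (curve[length(curve)] <= curve[1L]) "decreasing" else "increasing"
  }
  drop_k <- if (direction == "decreasing") {
    curve[-length(curve)] - curve[-1L]
  } else {
    curve[-1L] - curve[-length(curve)]
  }
  rel <- drop_k / pmax(abs(curve[-length(curve)]), eps)
  hit <- which(rel < rel_tol)
  if (length(hit) == 0L) {
    return(structure(length(curve), converged = FALSE))
  }
  structure(hit[1L], converged = TRUE)
}

#' Scan maximum path length K and collect fit diagnostics
#'
#' For each K in `1..k_max`: fits the mapping, predicts the functional
#' matrix, and records three agreement measures against the target — the
#' barcode measure [sse_beta()] (between the beta0 barcodes of the
#' 1 - |corr| dissimilarities of target and prediction), the Frobenius SSE,
#' and the Pearson correlation of node-pair entries. The elbow of the
#' SSE_beta curve selects K.
#'
#' @inheritParams fit_mapping
#' @param k_max largest path length scanned (`>= 1`).
#' @param rel_tol elbow threshold passed to [select_elbow()].
#' @return a tibble of class `sf_scan` with columns `k`, `sse_beta`,
#'   `frobenius_sse`, `pearson_r`, `mu`, and attributes `k_selected` and
#'   `elbow_converged`.
#' @export
scan_path_lengths <- function(s, f, k_max, mu = "gcv",
                              mu_grid = default_mu_grid(), rel_tol = 0.05) {
  k_max <- check_count(k_max, "k_max", min = 1L)
  target_bar <- betti0_barcode(dissimilarity_from_connectivity(f, quiet = TRUE))
  rows <- lapply(seq_len(k_max), function(k) {
    fit <- fit_mapping(s, f, k, mu = mu, mu_grid = mu_grid,
                       warn_spectral = FALSE)
    pred <- predict(fit, s)
    pred_bar <- betti0_barcode(
      dissimilarity_from_connectivity(pred, quiet = TRUE)
    )
    tibble::tibble(
      k = k,
      sse_beta = sse_beta(target_bar, pred_bar),
      frobenius_sse = frobenius_sse(f, pred),
      pearson_r = pearson_similarity(f, pred),
      mu = fit$mu
    )
  })
  out <- dplyr::bind_rows(rows)
  elbow <- select_elbow(out$sse_beta, rel_tol = rel_tol,
                        direction = "decreasing")
  attr(out, "k_selected") <- out$k[as.integer(elbow)]
  attr(out, "elbow_converged") <- attr(elbow, "converged")
  class(out) <- c("sf_scan", class(out))
  out
}

#' @rdname scan_path_lengths
#' @param scan an `sf_scan` tibble.
#' @export
k_selected <- function(scan) attr(scan, "k_selected")

#' Hop-count diameter of a structural graph
#'
#' Longest shortest path (in edge hops) over all node pairs, from
#' breadth-first search out of every node. Weighted input is binarized
#' first. A disconnected graph yields the diameter of its largest connected
#' component, flagged via attribute `disconnected = TRUE`.
#'
#' @param s a [connectivity_matrix()].
#' @return integer diameter with logical attribute `disconnected`.
#' @export
graph_diameter <- function(s) {
  stopifnot(is_connectivity_matrix(s))
  if (attr(s, "weighted")) s <- binarize(s)
  vals <- as_bare_matrix(s)
  if (nrow(vals) == 0L || sum(vals) == 0) {
    stop_validation("graph has no edges; diameter undefined.")
  }
  g <- igraph::graph_from_adjacency_matrix(vals, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)
  disconnected <- comp$no > 1L
  if (disconnected) {
    keep <- which(comp$membership == which.max(comp$csize))
    g <- igraph::induced_subgraph(g, keep)
  }
  d <- igraph::diameter(g, weights = NA)
  structure(as.integer(d), disconnected = disconnected)
}
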