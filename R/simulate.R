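#' Generate a modular (planted-partition) binary structural graph
#'
#' Stand-in for tractography-derived structural connectomes, which exhibit
#' modular community structure: nodes are split into `n_modules` contiguous
#' blocks of near-equal size, and each unordered pair is connected
#' independently with probability `p_within` (same block) or `p_between`
#' (different blocks). With `p_within == p_between` this reduces to an
#' Erdos-Renyi graph. Deterministic given `seed`.
#'
#' @param n_nodes number of nodes; default 66, a common low-resolution
#'   cortical parcellation size.
#' @param n_modules number of modules; each must hold at least 2 nodes.
#' @param p_within,p_between connection probabilities, with
#'   `0 <= p_between <= p_within <= 1`.
#' @param seed integer seed.
#' @return a binary structural [connectivity_matrix()].
#' @export
generate_modular_sc <- function(n_nodes = 66L, n_modules = 4L,
                                p_within = 0.6, p_between = 0.05, seed) {
  n_nodes <- check_count(n_nodes, "n_nodes", min = 2L)
  n_modules <- check_count(n_modules, "n_modules", min = 1L)
  if (n_nodes %/% n_modules < 2L) {
    stop_parameter("each module must contain at least 2 nodes.")
  }
  if (p_between > p_within || p_within > 1 || p_between < 0) {
    stop_parameter("need 0 <= p_between <= p_within <= 1.")
  }
  seed <- check_count(seed, "seed")
  membership <- sort(rep_len(seq_len(n_modules), n_nodes))
  same <- outer(membership, membership, "==")
  prob <- ifelse(same, p_within, p_between)
  vals <- matrix(0, n_nodes, n_nodes)
  iu <- which(upper.tri(vals))
  vals[iu] <- with_seed(seed, stats::rbinom(length(iu), 1L, prob[iu]))
  vals <- vals + t(vals)
  connectivity_matrix(vals, kind = "structural", weighted = FALSE)
}

#' Generate a functional matrix from the forward polynomial model
#'
#' Builds `F = G + sum_k c_k S^k + E` with known ground truth, where E is
#' symmetric Gaussian noise: independent draws on the vectorized unique
#' entries (diagonal included), mirrored so symmetry is exact. This is the
#' generative counterpart of [fit_mapping()], used to close the
#' recover-the-truth loop in tests. Deterministic given `seed`.
#'
#' @param s structural [connectivity_matrix()].
#' @param coefficients numeric vector `c0, c1, ..., cK*` of true
#'   path-length coefficients (length at most N).
#' @param global_input true global shared input G.
#' @param noise_sd standard deviation of the entrywise Gaussian noise;
#'   0 gives the exact forward model.
#' @param seed integer seed (used only when `noise_sd > 0`).
#' @return a functional [connectivity_matrix()].
#' @export
forward_model <- function(s, coefficients, global_input = 0, noise_sd = 0,
                          seed = 1L) {
  stopifnot(is_connectivity_matrix(s))
  if (length(coefficients) < 1L || length(coefficients) > nrow(s)) {
    stop_parameter("`coefficients` must have between 1 and N entries.")
  }
  if (noise_sd < 0) stop_parameter("`noise_sd` must be >= 0.")
  n <- nrow(s)
  sv <- as_bare_matrix(s)
  acc <- matrix(global_input, n, n) + coefficients[1L] * diag(n)
  pk <- diag(n)
  if (length(coefficients) > 1L) {
    for (k in 2:length(coefficients)) {
      pk <- pk %*% sv
      acc <- acc + coefficients[k] * pk
    }
  }
  if (noise_sd > 0) {
    ev <- with_seed(seed, stats::rnorm(n * (n + 1L) / 2L, 0, noise_sd))
    acc <- acc + unvectorize_lower(ev, n)
  }
  connectivity_matrix(acc, labels = node_labels(s), kind = "functional",
                      weighted = TRUE)
}

#' Generate a valid correlation matrix from a latent-factor model
#'
#' Simulates `20 * n_nodes` time points of `n_latent` independent latent
#' signals, mixes them into `n_nodes` channels with Gaussian loadings, adds
#' channel noise, and returns the channel-pairwise Pearson correlation
#' matrix — a simple emulation of resting-state functional connectivity.
#' Entries lie in \[-1, 1\], the diagonal is 1, and the matrix is positive
#' semidefinite by construction. Deterministic given `seed`.
#'
#' @param n_nodes number of channels/nodes.
#' @param n_latent number of shared latent signals (>= 1).
#' @param noise_sd channel noise standard deviation relative to unit-sd
#'   latent signals; larger values push correlations toward 0.
#' @param seed integer seed.
#' @return a functional [connectivity_matrix()].
#' @export
generate_correlation_matrix <- function(n_nodes, n_latent = 3L,
                                        noise_sd = 0.5, seed) {
  n_nodes <- check_count(n_nodes, "n_nodes", min = 2L)
  n_latent <- check_count(n_latent, "n_latent", min = 1L)
  if (noise_sd < 0) stop_parameter("`noise_sd` must be >= 0.")
  seed <- check_count(seed, "seed")
  vals <- with_seed(seed, {
    t_pts <- 20L * n_nodes
    latent <- matrix(stats::rnorm(t_pts * n_latent), t_pts, n_latent)
    mixing <- matrix(stats::rnorm(n_latent * n_nodes), n_latent, n_nodes)
    channels <- latent %*% mixing +
      noise_sd * matrix(stats::rnorm(t_pts * n_nodes), t_pts, n_nodes)
    stats::cor(channels)
  })
  vals <- pmin(pmax(vals, -1), 1)
  diag(vals) <- 1
  connectivity_matrix(vals, kind = "functional", weighted = TRUE)
}
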