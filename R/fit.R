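#' Fit the polynomial structure-to-function mapping
#'
#' Models the functional connectivity matrix F as a weighted sum of powers
#' of the structural matrix S plus a global shared input:
#' `F ~ G + c0 I + c1 S + c2 S^2 + ... + cK S^K`. The k = 0 term captures
#' local recurrent self-coupling, k = 1 the direct anatomical pathway, and
#' higher powers indirect pathways of length k. G models a brain-wide common
#' signal added to every entry. Because all matrices are symmetric, the fit
#' runs over the vectorized diagonal-plus-lower-triangle entries only. The
#' path-length coefficients are ridge-penalized (`mu * ||c||^2`); G is not.
#' Each power is max-abs normalized before fitting and the fitted
#' coefficients are divided by the same factors afterwards, so the returned
#' coefficients are on the original (unnormalized) power scale.
#'
#' A diagnostic warning reports the spectral radius of S when it is 1 or
#' larger: the polynomial expansion converges as a Taylor series only for
#' spectral radius below one, although the per-power normalization keeps the
#' finite-degree fit well scaled regardless.
#'
#' @param s structural [connectivity_matrix()].
#' @param f functional [connectivity_matrix()] with the same size and node
#'   labels as `s`.
#' @param k_max maximum path length K (`0 <= K <= N - 1`).
#' @param mu ridge weight: a single nonnegative number, or `"gcv"` to select
#'   it by [gcv_select()] on `mu_grid`.
#' @param mu_grid candidate grid used when `mu = "gcv"`; defaults to
#'   [default_mu_grid()].
#' @param n_boot if not `NULL`, number of bootstrap replicates (>= 100) used
#'   to attach 95% percentile confidence intervals via [bootstrap_ci()].
#' @param seed RNG seed for the bootstrap; required when `n_boot` is given.
#' @param warn_spectral warn when the spectral radius of S is >= 1.
#' @return an object of class `sf_mapping`: fitted coefficients `c0..cK` on
#'   the original power scale, `global_input` G, `mu` actually used, the
#'   scale factors `m_k`, the GCV curve when selected, optional bootstrap
#'   CIs, and fit summaries. Use [tidy()] / [glance()] to extract tibbles
#'   and [predict()] to rebuild a functional matrix.
#' @examples
#' s <- generate_modular_sc(30, 3, 0.6, 0.1, seed = 1)
#' f <- forward_model(s, coefficients = c(-0.3, 0.05, 0.01),
#'                    global_input = 0.01, noise_sd = 0, seed = 1)
#' fit <- fit_mapping(s, f, k_max = 2, mu = 1e-8)
#' tidy(fit)
#' @export
fit_mapping <- function(s, f, k_max, mu = "gcv", mu_grid = default_mu_grid(),
                        n_boot = NULL, seed = NULL, warn_spectral = TRUE) {
  stopifnot(is_connectivity_matrix(s), is_connectivity_matrix(f))
  if (!identical(dim(s), dim(f))) {
    stop_validation(sprintf(
      "structural (%d nodes) and functional (%d nodes) matrices differ in size.",
      nrow(s), nrow(f)
    ))
  }
  if (!identical(node_labels(s), node_labels(f))) {
    stop_validation("structural and functional node labels do not match.")
  }
  k_max <- check_count(k_max, "k_max")
  if (warn_spectral) {
    rho <- max(abs(eigen(as_bare_matrix(s), symmetric = TRUE,
                         only.values = TRUE)$values))
    if (rho >= 1) {
      warning(sprintf(
        "spectral radius of S is %.3g (>= 1); the polynomial series does not converge, though the finite-degree normalized fit remains well posed.",
        rho
      ), call. = FALSE)
    }
  }
  basis <- build_power_basis(s, k_max)
  x <- assemble_design(basis)
  y <- vectorize_lower(as_bare_matrix(f))
  penalized <- c(FALSE, rep(TRUE, k_max + 1L))

  gcv_curve <- NULL
  if (identical(mu, "gcv")) {
    sel <- gcv_select(x, y, mu_grid = mu_grid, penalized = penalized)
    mu_used <- sel$mu_star
    gcv_curve <- sel$gcv_curve
  } else {
    if (!is.numeric(mu) || length(mu) != 1L || mu < 0) {
      stop_parameter("`mu` must be a single nonnegative number or \"gcv\".")
    }
    mu_used <- mu
  }

  b <- solve_tikhonov(x, y, mu_used, penalized)
  global_input <- b[1L]
  coefficients <- b[-1L] / basis$scale_factors
  names(coefficients) <- paste0("c", 0:k_max)

  fitted <- drop(x %*% b)
  rss <- sum((y - fitted)^2)

  model <- structure(
    list(
      coefficients = coefficients,
      global_input = global_input,
      mu = mu_used,
      k_max = k_max,
      scale_factors = basis$scale_factors,
      gcv_curve = gcv_curve,
      ci = NULL,
      n_pairs = length(y),
      n_nodes = nrow(s),
      labels = node_labels(s),
      rss = rss,
      pearson_r = stats::cor(y, fitted)
    ),
    class = "sf_mapping"
  )

  if (!is.null(n_boot)) {
    if (is.null(seed)) stop_parameter("`seed` is required when `n_boot` is given.")
    model$ci <- bootstrap_ci(s, f, k_max, mu_used,
                             n_boot = n_boot, seed = seed)
  }
  model
}

#' @export
print.sf_mapping <- function(x, ...) {
  cat(sprintf(
    "<sf_mapping> K = %d, mu = %.3g, N = %d (%d node pairs)\n",
    x$k_max, x$mu, x$n_nodes, x$n_pairs
  ))
  cat(sprintf("  global input G = %.4g\n", x$global_input))
  cat("  coefficients (original power scale):\n")
  print(signif(x$coefficients, 4))
  cat(sprintf("  in-sample Pearson r = %.3f\n", x$pearson_r))
  invisible(x)
}

#' Predict a functional matrix from a fitted mapping
#'
#' Rebuilds `G * ones + sum_k c_k S^k` from freshly computed raw matrix
#' powers of the supplied structural matrix. `newdata` may differ from the
#' matrix used for fitting as long as `K <= N - 1`.
#'
#' @param object an `sf_mapping` fit.
#' @param newdata structural [connectivity_matrix()].
#' @param ... unused.
#' @return a functional [connectivity_matrix()].
#' @export
predict.sf_mapping <- function(object, newdata, ...) {
  stopifnot(is_connectivity_matrix(newdata))
  n <- nrow(newdata)
  if (object$k_max > n - 1L) {
    stop_parameter("model K exceeds N - 1 for the supplied matrix.")
  }
  sv <- as_bare_matrix(newdata)
  acc <- matrix(object$global_input, n, n)
  pk <- diag(n)
  acc <- acc + object$coefficients[1L] * pk
  if (object$k_max >= 1L) {
    for (k in seq_len(object$k_max)) {
      pk <- pk %*% sv
      acc <- acc + object$coefficients[k + 1L] * pk
    }
  }
  acc <- (acc + t(acc)) / 2  # guard symmetry against rounding
  connectivity_matrix(acc, labels = node_labels(newdata),
                      kind = "functional", weighted = TRUE)
}

#' Bootstrap confidence intervals for the mapping coefficients
#'
#' Resamples the `N(N+1)/2` vectorized (design-row, response) node-pair
#' entries with replacement, refits at fixed `mu` (never re-selected per
#' replicate), and reports percentile 95% intervals on the original
#' coefficient scale, including one for the global input G.
#'
#' @inheritParams fit_mapping
#' @param mu fixed ridge weight (a number, not `"gcv"`).
#' @param n_boot number of bootstrap replicates; at least 100 (fewer gives
#'   unreliable percentile intervals).
#' @param seed integer seed; results are deterministic given the seed.
#' @param level confidence level (default 0.95).
#' @return a tibble with columns `term` (`"G"`, `"c0"`, ...), `estimate`,
#'   `conf.low`, `conf.high`.
#' @export
bootstrap_ci <- function(s, f, k_max, mu, n_boot = 1000L, seed,
                         level = 0.95) {
  n_boot <- check_count(n_boot, "n_boot", min = 1L)
  if (n_boot < 100L) {
    stop_parameter("`n_boot` must be >= 100 for stable percentile intervals.")
  }
  if (!is.numeric(mu) || length(mu) != 1L || mu < 0) {
    stop_parameter("`mu` must be a fixed nonnegative number for the bootstrap.")
  }
  k_max <- check_count(k_max, "k_max")
  basis <- build_power_basis(s, k_max)
  x <- assemble_design(basis)
  y <- vectorize_lower(as_bare_matrix(f))
  penalized <- c(FALSE, rep(TRUE, k_max + 1L))
  n <- length(y)

  point <- solve_tikhonov(x, y, mu, penalized)
  draws <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      solve_tikhonov(x[idx, , drop = FALSE], y[idx], mu, penalized)
    }, numeric(ncol(x)))
  })
  # restore original power scale (G row unscaled)
  scale <- c(1, basis$scale_factors)
  draws <- draws / scale
  point <- point / scale
  alpha <- (1 - level) / 2
  qs <- apply(draws, 1L, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE)
  tibble::tibble(
    term = c("G", paste0("c", 0:k_max)),
    estimate = unname(point),
    conf.low = qs[1L, ],
    conf.high = qs[2L, ]
  )
}

#' Tidy and glance methods for fitted mappings
#'
#' `tidy()` returns one row per model term (global input first, then
#' `c0..cK`) with bootstrap intervals when present; `glance()` returns a
#' one-row fit summary.
#'
#' @param x an `sf_mapping` fit.
#' @param ... unused.
#' @return a tibble.
#' @method tidy sf_mapping
#' @export
tidy.sf_mapping <- function(x, ...) {
  out <- tibble::tibble(
    term = c("G", names(x$coefficients)),
    estimate = c(x$global_input, unname(x$coefficients))
  )
  if (!is.null(x$ci)) {
    out$conf.low <- x$ci$conf.low
    out$conf.high <- x$ci$conf.high
  }
  out
}

#' @rdname tidy.sf_mapping
#' @method glance sf_mapping
#' @export
glance.sf_mapping <- function(x, ...) {
  tibble::tibble(
    k_max = x$k_max,
    mu = x$mu,
    n_nodes = x$n_nodes,
    n_pairs = x$n_pairs,
    rss = x$rss,
    pearson_r = x$pearson_r
  )
}

#' Serialize a fitted mapping to JSON
#'
#' Writes K, mu, coefficients, G, scale factors, CIs (if any) and optional
#' provenance fields to a plain-text JSON document; [read_mapping()] loads
#' it back.
#'
#' @param model an `sf_mapping` fit.
#' @param path output path.
#' @param provenance optional named list (e.g. input checksums, seed).
#' @export
write_mapping <- function(model, path, provenance = NULL) {
  stopifnot(inherits(model, "sf_mapping"))
  doc <- list(
    format = "polyconn-mapping-v1",
    k_max = model$k_max,
    mu = model$mu,
    global_input = model$global_input,
    coefficients = as.list(model$coefficients),
    scale_factors = model$scale_factors,
    n_nodes = model$n_nodes,
    ci = if (!is.null(model$ci)) model$ci else NULL,
    provenance = provenance
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_mapping
#' @export
read_mapping <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "polyconn-mapping-v1")) {
    stop_format("not a polyconn mapping file.")
  }
  structure(
    list(
      coefficients = unlist(doc$coefficients),
      global_input = doc$global_input,
      mu = doc$mu,
      k_max = doc$k_max,
      scale_factors = doc$scale_factors,
      gcv_curve = NULL,
      ci = if (!is.null(doc$ci)) tibble::as_tibble(doc$ci) else NULL,
      n_pairs = doc$n_nodes * (doc$n_nodes + 1) / 2,
      n_nodes = doc$n_nodes,
      labels = NULL,
      rss = NA_real_,
      pearson_r = NA_real_
    ),
    class = "sf_mapping"
  )
}
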