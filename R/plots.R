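#' Plot a beta0 barcode as a step function
#'
#' Component count against the filtration value lambda; the curve starts at
#' N and steps down at each single-linkage merge height.
#'
#' @param object a `betti_barcode`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot betti_barcode
#' @export
autoplot.betti_barcode <- function(object, ...) {
  lam <- c(0, object$breakpoints, 1)
  df <- tibble::tibble(
    lambda = lam,
    beta0 = evaluate_barcode(object, pmin(lam + 1e-12, 1))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lambda, y = .data$beta0)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::labs(
      x = expression(lambda), y = expression(beta[0](lambda)),
      title = sprintf("beta0 barcode (N = %d)", object$n_nodes)
    ) +
    ggplot2::theme_minimal()
}

#' Plot path-length scan diagnostics
#'
#' One panel per measure (SSE_beta, Frobenius SSE, Pearson r) against K,
#' with the selected elbow marked.
#'
#' @param object an `sf_scan` tibble from [scan_path_lengths()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot sf_scan
#' @export
autoplot.sf_scan <- function(object, ...) {
  long <- tibble::tibble(
    k = rep(object$k, 3L),
    measure = rep(c("SSE_beta", "Frobenius SSE", "Pearson r"),
                  each = nrow(object)),
    value = c(object$sse_beta, object$frobenius_sse, object$pearson_r)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = attr(object, "k_selected"),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "maximum path length K", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.betti_barcode
#' @param b a `betti_barcode`.
#' @export
plot_barcode <- function(b) autoplot.betti_barcode(b)

#' @rdname autoplot.sf_scan
#' @param scan an `sf_scan` tibble.
#' @export
plot_scan <- function(scan) autoplot.sf_scan(scan)
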