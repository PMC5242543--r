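#' Connectivity matrix container
#'
#' A `connectivity_matrix` is a square symmetric numeric matrix carrying node
#' labels (as dimnames) plus two attributes: `kind` (`"structural"` or
#' `"functional"`) and `weighted` (logical). Structural matrices hold
#' anatomical connection strengths (e.g. streamline counts); functional
#' matrices hold temporal correlations between regional activity.
#'
#' Small asymmetries (up to `sym_tol`, absolute) are symmetrized as
#' `(M + t(M))/2`; larger ones are an error naming the worst offending entry
#' pair. Unweighted matrices must have off-diagonal entries in \{0, 1\}.
#'
#' @param values square numeric matrix of connection weights.
#' @param labels character vector of node identifiers, one per row; defaults
#'   to `"n0001"`, `"n0002"`, ... when `NULL`.
#' @param kind `"structural"` or `"functional"`.
#' @param weighted logical; if `NULL`, inferred from the entries (any
#'   off-diagonal value outside \{0, 1\} implies a weighted matrix).
#' @param sym_tol absolute tolerance for symmetrization on construction.
#' @return a `connectivity_matrix` object.
#' @examples
#' s <- connectivity_matrix(matrix(c(0, 1, 1, 0), 2))
#' node_labels(s)
#' @export
connectivity_matrix <- function(values,
                                labels = NULL,
                                kind = c("structural", "functional"),
                                weighted = NULL,
                                sym_tol = 1e-9) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_format("`values` must be a numeric matrix.")
  }
  if (nrow(values) != ncol(values)) {
    stop_format(sprintf(
      "connectivity matrix must be square; got %d x %d.",
      nrow(values), ncol(values)
    ))
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop_validation(sprintf(
      "non-finite entry at row %d, column %d.", bad[1L], bad[2L]
    ))
  }
  asym <- abs(values - t(values))
  if (max(asym) > sym_tol) {
    worst <- which(asym == max(asym), arr.ind = TRUE)[1L, ]
    stop_validation(sprintf(
      "matrix is asymmetric beyond tolerance %g: |M[%d,%d] - M[%d,%d]| = %g.",
      sym_tol, worst[1L], worst[2L], worst[2L], worst[1L], max(asym)
    ))
  }
  values <- (values + t(values)) / 2
  n <- nrow(values)
  if (is.null(labels)) labels <- default_node_labels(n)
  labels <- as.character(labels)
  if (length(labels) != n) {
    stop_validation(sprintf(
      "expected %d node labels, got %d.", n, length(labels)
    ))
  }
  if (anyDuplicated(labels)) {
    stop_validation("node labels must be unique.")
  }
  off <- values[row(values) != col(values)]
  if (is.null(weighted)) weighted <- !all(off %in% c(0, 1))
  if (!weighted && !all(off %in% c(0, 1))) {
    stop_validation(
      "matrix flagged unweighted but has off-diagonal entries outside {0, 1}."
    )
  }
  dimnames(values) <- list(labels, labels)
  structure(values,
    kind = kind, weighted = weighted,
    class = c("connectivity_matrix", "matrix", "array")
  )
}

default_node_labels <- function(n) sprintf("n%04d", seq_len(n))

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf(
    "<connectivity_matrix> %d nodes, %s, %s; %d off-diagonal edges\n",
    nrow(x), attr(x, "kind"),
    if (attr(x, "weighted")) "weighted" else "binary",
    sum(x[upper.tri(x)] != 0)
  ))
  invisible(x)
}

#' @rdname connectivity_matrix
#' @param x a `connectivity_matrix`.
#' @export
node_labels <- function(x) rownames(x)

#' @rdname connectivity_matrix
#' @export
is_connectivity_matrix <- function(x) inherits(x, "connectivity_matrix")

# strip class/attrs down to a bare numeric matrix
as_bare_matrix <- function(x) {
  x <- unclass(x)
  attr(x, "kind") <- NULL
  attr(x, "weighted") <- NULL
  x
}

#' Read a connectivity matrix from a dense delimited text file
#'
#' One matrix row per line. The delimiter (comma, tab, or whitespace) is
#' auto-detected from the first line unless given. An optional sidecar file
#' supplies one node label per line.
#'
#' @param path path to the matrix file.
#' @param delimiter single character, or `NULL` to auto-detect.
#' @param labels_path optional path to a one-label-per-line sidecar.
#' @inheritParams connectivity_matrix
#' @return a validated [connectivity_matrix()].
#' @export
read_matrix <- function(path, delimiter = NULL, labels_path = NULL,
                        kind = c("structural", "functional"),
                        sym_tol = 1e-9) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_format(sprintf("empty matrix file: %s", path))
  if (is.null(delimiter)) delimiter <- detect_delimiter(lines[[1L]])
  split_re <- if (delimiter == " ") "[ \t]+" else delimiter
  rows <- lapply(lines, function(l) strsplit(trimws(l), split_re)[[1L]])
  widths <- lengths(rows)
  if (length(unique(widths)) != 1L) {
    stop_format(sprintf(
      "ragged rows: line 1 has %d fields but line %d has %d.",
      widths[1L], which(widths != widths[1L])[1L],
      widths[widths != widths[1L]][1L]
    ))
  }
  vals <- suppressWarnings(
    vapply(rows, function(r) as.numeric(r), numeric(widths[1L]))
  )
  vals <- t(matrix(vals, nrow = widths[1L]))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop_parse(sprintf(
      "non-numeric cell at row %d, column %d.", bad[1L], bad[2L]
    ))
  }
  if (nrow(vals) != ncol(vals)) {
    stop_format(sprintf(
      "matrix file is not square: %d rows x %d columns.",
      nrow(vals), ncol(vals)
    ))
  }
  labels <- NULL
  if (!is.null(labels_path)) {
    labels <- trimws(readLines(labels_path, warn = FALSE))
    labels <- labels[nzchar(labels)]
  }
  connectivity_matrix(vals, labels = labels, kind = kind, sym_tol = sym_tol)
}

detect_delimiter <- function(line) {
  if (grepl(",", line, fixed = TRUE)) return(",")
  if (grepl("\t", line, fixed = TRUE)) return("\t")
  " "
}

#' Write a connectivity matrix as dense delimited text
#'
#' Entries are written with 17 significant digits so a read/write round trip
#' reproduces values to better than 1e-12. Labels go to a sidecar file when
#' `labels_path` is given.
#'
#' @param m a [connectivity_matrix()].
#' @param path output file path.
#' @param delimiter field separator (default comma).
#' @param labels_path optional sidecar path for node labels.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, delimiter = ",", labels_path = NULL) {
  stopifnot(is_connectivity_matrix(m))
  vals <- as_bare_matrix(m)
  lines <- apply(vals, 1L, function(r) {
    paste(sprintf("%.17g", r), collapse = delimiter)
  })
  ok <- tryCatch(
    {
      writeLines(lines, path)
      TRUE
    },
    error = function(e) e
  )
  if (!isTRUE(ok)) stop_format(sprintf("cannot write to %s: %s",
                                       path, conditionMessage(ok)))
  if (!is.null(labels_path)) writeLines(node_labels(m), labels_path)
  invisible(path)
}

#' Binarize a connectivity matrix
#'
#' Off-diagonal entries become 1 wherever the weight is nonzero, 0 elsewhere;
#' the diagonal is forced to 0 (self-connections are not anatomical edges).
#' The binary matrix therefore has exactly the same number of edges as the
#' weighted original. Idempotent.
#'
#' @param m a [connectivity_matrix()].
#' @return a binary `connectivity_matrix` of the same kind and labels.
#' @export
binarize <- function(m) {
  stopifnot(is_connectivity_matrix(m))
  vals <- as_bare_matrix(m)
  vals <- (vals != 0) * 1
  diag(vals) <- 0
  connectivity_matrix(vals,
    labels = node_labels(m), kind = attr(m, "kind"), weighted = FALSE
  )
}

#' Bundle a structural/functional matrix pair into one compressed file
#'
#' Serializes both matrices, their labels and kinds into a single compressed
#' RDS container. Intended for large parcellations (thousands of nodes) where
#' dense text I/O is slow; the text reader/writer remains available.
#'
#' @param s,f structural and functional [connectivity_matrix()] objects.
#' @param path output `.rds` path.
#' @export
write_bundle <- function(s, f, path) {
  stopifnot(is_connectivity_matrix(s), is_connectivity_matrix(f))
  saveRDS(list(
    format = "polyconn-bundle-v1",
    s = list(values = as_bare_matrix(s), labels = node_labels(s),
             weighted = attr(s, "weighted")),
    f = list(values = as_bare_matrix(f), labels = node_labels(f),
             weighted = attr(f, "weighted"))
  ), path, compress = "gzip")
  invisible(path)
}

#' @rdname write_bundle
#' @return `read_bundle()` returns a list with elements `s` and `f`.
#' @export
read_bundle <- function(path) {
  b <- readRDS(path)
  if (!identical(b$format, "polyconn-bundle-v1")) {
    stop_format("not a polyconn bundle file.")
  }
  list(
    s = connectivity_matrix(b$s$values, labels = b$s$labels,
                            kind = "structural", weighted = b$s$weighted),
    f = connectivity_matrix(b$f$values, labels = b$f$labels,
                            kind = "functional", weighted = b$f$weighted)
  )
}
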