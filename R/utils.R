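# classed error helpers so callers can distinguish failure modes
stop_format <- function(msg) {
  rlang::abort(msg, class = "polyconn_format_error")
}
stop_parse <- function(msg) {
  rlang::abort(msg, class = "polyconn_parse_error")
}
stop_validation <- function(msg) {
  rlang::abort(msg, class = "polyconn_validation_error")
}
stop_parameter <- function(msg) {
  rlang::abort(msg, class = "polyconn_parameter_error")
}

# run expr under a local RNG state seeded with `seed`; restores the caller's
# RNG afterwards so seeded helpers do not perturb user-level randomness
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

check_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x) ||
      x < min) {
    stop_parameter(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}
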