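# Internal helpers: classed conditions and reproducible RNG scoping.

sdms_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "sdms_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

stop_validation <- function(...) sdms_stop(sprintf(...), "sdms_validation_error")
stop_parse      <- function(...) sdms_stop(sprintf(...), "sdms_parse_error")
stop_degenerate <- function(...) sdms_stop(sprintf(...), "sdms_degeneracy_error")
stop_usage      <- function(...) sdms_stop(sprintf(...), "sdms_usage_error")
stop_io         <- function(...) sdms_stop(sprintf(...), "sdms_io_error")

# Evaluate `code` under set.seed(seed), restoring the caller's RNG stream.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

is_count <- function(x, min = 0) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == trunc(x) && x >= min
}

is_number <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)

check_numeric_vector <- function(x, name, min_len = 1L) {
  if (!is.numeric(x) || length(x) < min_len) {
    stop_validation("'%s' must be a numeric vector of length >= %d", name, min_len)
  }
  if (any(!is.finite(x))) {
    stop_validation("'%s' contains non-finite values", name)
  }
  invisible(x)
}
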