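# internal helpers shared across stages

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop_config("'%s' must be TRUE or FALSE", name)
  x
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) || x < min)
    stop_config("'%s' must be a single integer >= %d", name, min)
  as.integer(x)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open_lower) x > lower else x >= lower) &&
    (if (open_upper) x < upper else x <= upper)
  if (!ok)
    stop_config("'%s' must be a single number in %s%s, %s%s", name,
                if (open_lower) "(" else "[", format(lower),
                format(upper), if (open_upper) ")" else "]")
  as.numeric(x)
}

# run `expr` under a fixed RNG state, restoring the caller's state afterwards
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# symmetric-matrix sanity used by the network stages
check_symmetric_unit <- function(m, name, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop_config("'%s' must be a square matrix", name)
  if (max(abs(m - t(m))) > tol)
    stop_config("'%s' must be symmetric", name)
  if (min(m) < -tol || max(m) > 1 + tol)
    stop_config("'%s' must have entries in [0, 1]", name)
  invisible(m)
}
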