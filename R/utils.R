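# internal helpers shared across the package

#' Evaluate an expression under a local RNG state
#'
#' Sets the seed, runs `expr`, and restores the caller's `.Random.seed`, so
#' package functions never leak RNG state into the session.
#' @noRd
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    if (length(seed) != 1L || is.na(seed)) stop("'seed' must be a single integer")
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# Deterministic 31-bit hash of a character id mixed with a user seed.
# Used to key per-animal / per-marker initialisation so that results are
# invariant to row order (the draw depends on the id, not on its position).
id_seed <- function(id, seed) {
  m <- 2147483647  # 2^31 - 1
  h <- (as.double(seed) %% m)
  for (code in utf8ToInt(as.character(id))) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stopf("'%s' must be a single finite number", name)
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stopf("'%s' = %g is outside the admissible range %s%g, %g%s", name, x,
          if (open_lower) "(" else "[", lower, upper,
          if (open_upper) ")" else "]")
  invisible(x)
}
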