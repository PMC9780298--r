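# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Restores the caller's RNG state afterwards so generators are deterministic
#' given `seed` without clobbering the global stream.
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

#' @noRd
assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (strict_lower && x <= lower) {
    stop(sprintf("`%s` must be > %s", name, lower), call. = FALSE)
  }
  if (!strict_lower && x < lower) {
    stop(sprintf("`%s` must be >= %s", name, lower), call. = FALSE)
  }
  if (x > upper) {
    stop(sprintf("`%s` must be <= %s", name, upper), call. = FALSE)
  }
  invisible(x)
}

#' Odd rolling-median window size from a fraction of n
#' @noRd
odd_window <- function(n, frac) {
  k <- max(3L, as.integer(round(frac * n)))
  if (k %% 2L == 0L) k <- k + 1L
  min(k, if (n %% 2L == 1L) n else n - 1L)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
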