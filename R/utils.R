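# internal helpers shared across modules

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random stream. seed = NULL runs on the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic per-session sub-seed below 2^31, mixed from the master seed
# and the session coordinates so sessions can be rendered independently.
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) h <- (h * 7919 + (as.numeric(p) %% 104729) + 1) %% 2147483629
  as.integer(h) + 1L
}

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid("`%s` must be a finite numeric scalar", name)
  if (strict_lower && x <= lower)
    stop_invalid("`%s` must be > %g (got %g)", name, lower, x)
  if (!strict_lower && x < lower)
    stop_invalid("`%s` must be >= %g (got %g)", name, lower, x)
  if (x > upper)
    stop_invalid("`%s` must be <= %g (got %g)", name, upper, x)
  invisible(x)
}

rms <- function(x) sqrt(mean(x^2))
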