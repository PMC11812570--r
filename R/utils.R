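#' @keywords internal
"_PACKAGE"

# Internal argument checks ---------------------------------------------------

stop_arg <- function(...) stop(sprintf(...), call. = FALSE)

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE,
                         integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_arg("'%s' must be a single finite number", name)
  if (positive && x <= 0) stop_arg("'%s' must be > 0", name)
  if (nonneg && x < 0) stop_arg("'%s' must be >= 0", name)
  if (integerish && abs(x - round(x)) > 1e-8)
    stop_arg("'%s' must be a whole number", name)
  invisible(x)
}

check_fractions <- function(fractions, tol = 1e-9) {
  if (!is.numeric(fractions) || length(fractions) < 1L)
    stop_arg("'fractions' must be a non-empty numeric vector")
  if (any(fractions < 0))
    stop_arg("'fractions' must be non-negative")
  if (abs(sum(fractions) - 1) > tol)
    stop_arg("'fractions' must sum to 1 (got %.12f)", sum(fractions))
  invisible(fractions)
}

# Seed handling: every stochastic entry point takes an explicit `seed`.
# `NULL` leaves the RNG stream alone; an integer gives reproducible output
# without disturbing the caller's stream afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  check_scalar(seed, "seed", integerish = TRUE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic fan-out of one run seed into per-stage seeds (< 2^31).
derive_seed <- function(seed, index) {
  check_scalar(seed, "seed", integerish = TRUE)
  as.integer((abs(seed) * 7919 + 104729 * index) %% 2147483646 + 1)
}
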