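# Internal helpers: condition classes, tolerances, seeded RNG.

# Relative tolerance used for tie/argmax detection throughout: all model
# quantities are O(1)-O(1e3), so a relative 1e-9 band is far below any
# economically meaningful difference.
.REL_TOL <- 1e-9

abort_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("evomanage_validation_error", "error")))
}

abort_usage <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("evomanage_usage_error", "error")))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_validation("`%s` must be a single finite number", name)
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort_validation("`%s` = %g is outside the valid range %s%g, %g%s",
                     name, x,
                     if (strict_lower) "(" else "[", lower, upper,
                     if (strict_upper) ")" else "]")
  }
  invisible(x)
}

near <- function(a, b, tol = .REL_TOL) {
  abs(a - b) <= tol * max(1, abs(a), abs(b))
}

# Run `expr` under a fixed seed (if non-NULL) without disturbing the
# caller's RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort_validation("`seed` must be a single integer")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
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
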