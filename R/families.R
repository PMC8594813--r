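#' Parametric function families for profits and persistence
#'
#' Scenario and game configurations describe profit and persistence curves
#' as named parametric families so that they can be written to and read
#' back from YAML/JSON without loss. Four families are supported:
#'
#' * `constant`: `f(x) = value`.
#' * `linear`: `f(x) = intercept + slope * x`.
#' * `logistic`: `f(x) = lower + (upper - lower) / (1 + exp(-steepness * (x - midpoint)))`.
#' * `table`: linear interpolation through the points `(x, y)`;
#'   evaluation outside `range(x)` is an error.
#'
#' Arbitrary R functions may be used programmatically wherever a
#' `parametric_fn` is accepted, but only named families can be serialized.
#'
#' @param family One of `"constant"`, `"linear"`, `"logistic"`, `"table"`.
#' @param params Named list of family parameters (see above).
#' @return A function of one numeric (vectorized) argument, of class
#'   `parametric_fn`, carrying its family and parameters as attributes.
#' @examples
#' f <- parametric_fn("linear", list(intercept = 100, slope = -40))
#' f(c(0, 0.2, 1))
#' @export
parametric_fn <- function(family, params = list()) {
  family <- match.arg(family, c("constant", "linear", "logistic", "table"))
  need <- function(keys) {
    missing <- setdiff(keys, names(params))
    if (length(missing)) {
      abort_validation("family '%s' requires parameter(s): %s",
                       family, paste(missing, collapse = ", "))
    }
    extra <- setdiff(names(params), keys)
    if (length(extra)) {
      abort_validation("family '%s' does not accept parameter(s): %s",
                       family, paste(extra, collapse = ", "))
    }
  }
  f <- switch(family,
    constant = {
      need("value")
      v <- check_number(params$value, "value")
      function(x) rep_len(v, length(x))
    },
    linear = {
      need(c("intercept", "slope"))
      a <- check_number(params$intercept, "intercept")
      b <- check_number(params$slope, "slope")
      function(x) a + b * x
    },
    logistic = {
      need(c("lower", "upper", "midpoint", "steepness"))
      lo <- check_number(params$lower, "lower")
      hi <- check_number(params$upper, "upper")
      mid <- check_number(params$midpoint, "midpoint")
      k <- check_number(params$steepness, "steepness")
      function(x) lo + (hi - lo) / (1 + exp(-k * (x - mid)))
    },
    table = {
      need(c("x", "y"))
      xs <- as.numeric(params$x)
      ys <- as.numeric(params$y)
      if (length(xs) < 2L || length(xs) != length(ys) ||
          anyNA(xs) || anyNA(ys) || is.unsorted(xs, strictly = TRUE)) {
        abort_validation(
          "family 'table' requires strictly increasing `x` and matching `y`")
      }
      interp <- stats::approxfun(xs, ys, rule = 1)
      function(x) {
        if (any(x < xs[1L] - .REL_TOL | x > xs[length(xs)] + .REL_TOL)) {
          abort_validation("table family evaluated outside [%g, %g]",
                           xs[1L], xs[length(xs)])
        }
        interp(pmin(pmax(x, xs[1L]), xs[length(xs)]))
      }
    }
  )
  structure(f, class = c("parametric_fn", "function"),
            family = family, params = params)
}

# Accept a parametric_fn, a plain function, or a single number (treated as
# a constant curve); return something callable with serialization attrs
# where available.
as_curve <- function(x, name) {
  if (inherits(x, "parametric_fn")) return(x)
  if (is.function(x)) {
    return(structure(x, class = c("parametric_fn", "function"),
                     family = "custom", params = NULL))
  }
  if (is.numeric(x) && length(x) == 1L && is.finite(x)) {
    return(parametric_fn("constant", list(value = x)))
  }
  if (is.list(x) && !is.null(x$family)) {
    return(parametric_fn(x$family, x$params %||% list()))
  }
  abort_validation(
    "`%s` must be a parametric_fn, a function, a number, or a {family, params} list",
    name)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

curve_spec <- function(f) {
  fam <- attr(f, "family")
  if (is.null(fam) || identical(fam, "custom")) {
    abort_validation("custom R functions cannot be serialized; use a named family")
  }
  list(family = fam, params = attr(f, "params"))
}
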