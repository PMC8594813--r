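#' Optimal stewardship level for an isolated manager
#'
#' Chooses the action maximizing the present value `V(gamma) = E(gamma) *
#' L(gamma)` of the excess-profit stream. Finite action sets are evaluated
#' exhaustively. Continuous sets are scanned on a grid (default 1001
#' points) and, with `refine = TRUE`, polished by golden-section search in
#' the bracket around the best grid point (tolerance `1e-8` in `gamma`).
#' Ties are broken toward smaller `gamma` (less stewardship), consistent
#' with the strict-inequality benefit criterion.
#'
#' Grid-plus-golden-section is used rather than derivative-based search
#' because `V(gamma)` need not be smooth (tabulated profit or persistence
#' curves are piecewise linear) and need not be unimodal.
#'
#' @param scenario A [management_scenario()].
#' @param grid_size Number of grid points for continuous action sets.
#' @param refine Whether to refine the best continuous grid point by
#'   golden-section search.
#' @return An `optimization_result`: `optimal_action`, `optimal_value`,
#'   the probed `value_profile` (a tibble of gamma, E, L, V) and the
#'   `method` used.
#' @export
optimal_action <- function(scenario, grid_size = 1001L, refine = TRUE) {
  stopifnot(inherits(scenario, "management_scenario"))
  grid <- probe_actions(scenario$actions, grid_size)
  E <- scenario$pristine_profit(grid) - scenario$evolved_profit
  dk <- scenario$delta * scenario$persistence(grid)
  if (any(dk >= 1)) {
    abort_validation("non-finite lifespan on the action grid (delta * kappa = 1)")
  }
  L <- 1 / (1 - dk)
  V <- E * L
  if (all(!is.finite(V))) abort_validation("no action yields a finite value")

  best <- max(V)
  cand <- grid[V >= best - .REL_TOL * max(1, abs(best))]
  g_star <- min(cand)
  v_star <- best
  method <- "grid"

  if (scenario$actions$type == "interval" && refine) {
    step <- diff(scenario$actions$bounds) / (grid_size - 1)
    lo <- max(scenario$actions$bounds[1L], g_star - step)
    hi <- min(scenario$actions$bounds[2L], g_star + step)
    vfun <- function(g) {
      (scenario$pristine_profit(g) - scenario$evolved_profit) /
        (1 - scenario$delta * scenario$persistence(g))
    }
    opt <- stats::optimize(vfun, c(lo, hi), maximum = TRUE, tol = 1e-8)
    if (opt$objective > v_star + .REL_TOL * max(1, abs(v_star))) {
      g_star <- opt$maximum
      v_star <- opt$objective
    }
    method <- "refined"
  }

  structure(
    list(optimal_action = g_star, optimal_value = v_star,
         value_profile = tibble::tibble(gamma = grid, E = E, L = L, V = V),
         method = method),
    class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  cat("<optimization_result>\n")
  cat(sprintf("  optimal action gamma* = %.6g, value V* = %.6g (%s)\n",
              x$optimal_action, x$optimal_value, x$method))
  invisible(x)
}

#' Critical discount factor for a stewardship action
#'
#' For a fixed percentage cost of stewardship `c` (the ratio of forgone
#' pristine profit to the excess profit under stewardship) the incentive
#' side of the expanded inequality,
#' `delta * (kappa_gamma - kappa_gamma0) / (1 - delta * kappa_gamma)`,
#' increases from 0 as `delta` grows: there is a critical discount factor
#' above which stewardship pays. Solving at equality gives the closed form
#' `delta* = c / (kappa_gamma - kappa_gamma0 + c * kappa_gamma)`.
#'
#' Stewardship is infeasible at any discounting when even the patient
#' limit `delta -> 1` fails, i.e. when
#' `(kappa_gamma - kappa_gamma0) / (1 - kappa_gamma) <= c`, and likewise
#' whenever the action does not slow evolution (`kappa_gamma <=
#' kappa_gamma0`) but costs something.
#'
#' @param kappa_gamma,kappa_gamma0 Annual persistence under stewardship
#'   and under no stewardship.
#' @param cost_ratio Percentage cost `c >= 0` of stewardship (right-hand
#'   side of the expanded inequality).
#' @return A `critical_discount`: list with `feasible`, `delta_star`, and
#'   the companion interest rate `rate_star = 1/delta_star - 1` (both
#'   `NA` when infeasible).
#' @examples
#' critical_discount_factor(0.95, 0.8, 0.25)  # delta* about 0.645
#' @export
critical_discount_factor <- function(kappa_gamma, kappa_gamma0, cost_ratio) {
  check_number(kappa_gamma, "kappa_gamma", lower = 0, upper = 1)
  check_number(kappa_gamma0, "kappa_gamma0", lower = 0, upper = 1)
  check_number(cost_ratio, "cost_ratio", lower = 0)

  if (cost_ratio == 0) {
    out <- list(feasible = TRUE, delta_star = 0, rate_star = Inf)
  } else if (kappa_gamma <= kappa_gamma0) {
    out <- list(feasible = FALSE, delta_star = NA_real_, rate_star = NA_real_)
  } else {
    # delta -> 1 limit of the incentive is (k - k0)/(1 - k); if that
    # cannot cover the cost no admissible delta can.
    limit_ok <- if (kappa_gamma < 1) {
      (kappa_gamma - kappa_gamma0) / (1 - kappa_gamma) > cost_ratio
    } else TRUE
    if (!limit_ok) {
      out <- list(feasible = FALSE, delta_star = NA_real_,
                  rate_star = NA_real_)
    } else {
      ds <- cost_ratio /
        (kappa_gamma - kappa_gamma0 + cost_ratio * kappa_gamma)
      out <- list(feasible = TRUE, delta_star = ds,
                  rate_star = 1 / ds - 1)
    }
  }
  structure(out, class = "critical_discount")
}

#' @export
print.critical_discount <- function(x, ...) {
  if (x$feasible) {
    cat(sprintf(
      "critical discount factor delta* = %.6g (interest rate r* = %.6g/yr)\n",
      x$delta_star, x$rate_star))
  } else {
    cat("infeasible: no discount factor below 1 makes this action beneficial\n")
  }
  invisible(x)
}

#' Comparative statics of the stewardship incentive
#'
#' Sweeps one model primitive and reports the incentive gap (left minus
#' right side of the expanded inequality) along the sweep, together with
#' its verified monotonicity direction. Three sweeps are supported, each
#' with a known direction:
#'
#' * `"delta"`: less discounting of the future raises the incentive
#'   (nondecreasing gap).
#' * `"kappa_gamma"`: more effective management (larger
#'   `kappa(gamma) - kappa(gamma0)`) raises the incentive.
#' * `"pi_bar"`: a richer evolved state (higher fallback profit) lowers
#'   the incentive (nonincreasing gap).
#'
#' A sweep that violates its known direction indicates an implementation
#' bug and raises an internal-consistency error.
#'
#' @param scenario A [management_scenario()].
#' @param gamma Stewardship action being assessed (vs the scenario's
#'   `gamma0`).
#' @param parameter One of `"delta"`, `"kappa_gamma"`, `"pi_bar"`.
#' @param grid Optional numeric grid for the swept parameter; a sensible
#'   in-range default is built otherwise.
#' @return A list with a tibble `sweep` (`value`, `lhs`, `rhs`, `gap`)
#'   and the string `direction` (`"nondecreasing"` or `"nonincreasing"`).
#' @export
comparative_statics <- function(scenario, gamma,
                                parameter = c("delta", "kappa_gamma", "pi_bar"),
                                grid = NULL) {
  stopifnot(inherits(scenario, "management_scenario"))
  parameter <- match.arg(parameter)
  g0 <- scenario$gamma0
  pig <- scenario$pristine_profit(gamma)
  pig0 <- scenario$pristine_profit(g0)
  pibar <- scenario$evolved_profit
  kg <- scenario$persistence(gamma)
  kg0 <- scenario$persistence(g0)
  if (kg < kg0 - .REL_TOL) {
    abort_validation(
      "comparative statics describe stewardship actions: kappa(gamma) = %g must be >= kappa(gamma0) = %g",
      kg, kg0)
  }

  if (is.null(grid)) {
    grid <- switch(parameter,
      delta = seq(0, 0.99, length.out = 100),
      kappa_gamma = seq(kg0, 1, length.out = 100),
      pi_bar = seq(pibar - (pig - pibar),
                   pig - 1e-6 * max(1, abs(pig)), length.out = 100))
  }
  eval_at <- function(v) {
    vals <- switch(parameter,
      delta = evaluate_action_expanded(v, kg, kg0, pig, pig0, pibar),
      kappa_gamma = evaluate_action_expanded(scenario$delta, v, kg0, pig,
                                             pig0, pibar),
      pi_bar = evaluate_action_expanded(scenario$delta, kg, kg0, pig, pig0, v))
    c(vals$lhs, vals$rhs)
  }
  m <- vapply(grid, eval_at, numeric(2))
  sweep <- tibble::tibble(value = grid, lhs = m[1L, ], rhs = m[2L, ],
                          gap = m[1L, ] - m[2L, ])

  expected <- if (parameter == "pi_bar") "nonincreasing" else "nondecreasing"
  d <- diff(sweep$gap)
  tol <- .REL_TOL * max(1, max(abs(sweep$gap)))
  ok <- if (expected == "nondecreasing") all(d >= -tol) else all(d <= tol)
  if (!ok) {
    stop(sprintf(
      "internal consistency error: incentive sweep in `%s` is not %s",
      parameter, expected))
  }
  list(sweep = sweep, parameter = parameter, direction = expected)
}
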