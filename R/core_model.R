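#' Action sets
#'
#' A management scenario's action set is either a finite grid of candidate
#' stewardship levels or the continuous interval `[lower, upper]` (a refuge
#' fraction, a drug-combination intensity, ...). A bare numeric vector
#' passed to [management_scenario()] is interpreted as a grid.
#'
#' @param values Numeric vector of candidate actions (grid).
#' @param lower,upper Interval endpoints.
#' @return An action-set object.
#' @export
action_grid <- function(values) {
  values <- sort(unique(as.numeric(values)))
  if (length(values) < 1L || anyNA(values) || any(!is.finite(values))) {
    abort_validation("action grid must contain at least one finite value")
  }
  structure(list(type = "grid", values = values), class = "evo_actions")
}

#' @rdname action_grid
#' @export
action_interval <- function(lower = 0, upper = 1) {
  check_number(lower, "lower")
  check_number(upper, "upper")
  if (lower >= upper) abort_validation("interval requires lower < upper")
  structure(list(type = "interval", bounds = c(lower, upper)),
            class = "evo_actions")
}

as_actions <- function(x) {
  if (inherits(x, "evo_actions")) return(x)
  if (is.numeric(x)) return(action_grid(x))
  if (is.list(x) && identical(x$type, "interval")) {
    b <- as.numeric(x$bounds)
    return(action_interval(b[1L], b[2L]))
  }
  if (is.list(x) && identical(x$type, "grid")) {
    return(action_grid(as.numeric(x$values)))
  }
  abort_validation("`actions` must be a numeric grid or an action_interval()")
}

# Representative probe grid over an action set (used for validation,
# argmax and optimization).
probe_actions <- function(actions, n = 1001L) {
  if (actions$type == "grid") actions$values
  else seq(actions$bounds[1L], actions$bounds[2L], length.out = n)
}

action_in_set <- function(gamma, actions) {
  if (actions$type == "grid") {
    any(vapply(actions$values, function(v) near(v, gamma), logical(1)))
  } else {
    gamma >= actions$bounds[1L] - .REL_TOL &&
      gamma <= actions$bounds[2L] + .REL_TOL
  }
}

#' Define a manager's economic environment
#'
#' Bundles everything needed to value stewardship for one decision-maker:
#' annual discounting, the pristine-state profit curve \eqn{\Pi(\gamma)},
#' the evolved-state profit \eqn{\bar\Pi}, the annual persistence
#' probability \eqn{\kappa(\gamma)} that adverse evolution does *not*
#' occur, and the set of available actions \eqn{\Gamma}.
#'
#' The model treats adverse evolution (resistance spread, efficacy loss)
#' as an irreversible regime shift: while the system is pristine the
#' manager earns \eqn{\Pi(\gamma)} per year; once evolved, profit drops to
#' the constant \eqn{\bar\Pi} and stewardship stops. The excess profit
#' \eqn{E(\gamma) = \Pi(\gamma) - \bar\Pi} persists from one year to the
#' next with probability \eqn{\kappa(\gamma)}, so the stream's total
#' present value is \eqn{E(\gamma) L(\gamma)} with effective life span
#' \eqn{L(\gamma) = 1/(1 - \delta \kappa(\gamma))}.
#'
#' The no-stewardship action `gamma0` is defined as the maximizer of
#' \eqn{E(\gamma)} (equivalently of \eqn{\Pi(\gamma)}): the choice a
#' manager who ignores evolution would make. It is recomputed from the
#' profit curve; if a pinned value disagrees with the recomputed argmax a
#' warning is raised and the pinned value kept.
#'
#' @param pristine_profit Annual profit in the pristine state as a function
#'   of the action: a [parametric_fn()], a plain function, or a number
#'   (constant).
#' @param evolved_profit Constant annual profit after adverse evolution.
#' @param persistence Annual probability that adverse evolution does not
#'   occur, as a function of the action (same accepted forms). Values must
#'   lie in `[0, 1]`.
#' @param actions The action set: a numeric grid, [action_grid()], or
#'   [action_interval()].
#' @param rate Annual interest rate `r >= 0`. Exactly one of `rate` and
#'   `discount_factor` is required unless both agree via
#'   `delta = 1/(1 + r)`.
#' @param discount_factor Annual discount factor `delta` in `[0, 1)`.
#' @param gamma0 Optional pinned no-stewardship action.
#' @return An object of class `management_scenario`.
#' @examples
#' sc <- management_scenario(
#'   pristine_profit = parametric_fn("linear", list(intercept = 100, slope = -40)),
#'   evolved_profit  = 60,
#'   persistence     = parametric_fn("linear", list(intercept = 0.8, slope = 0.15)),
#'   actions         = action_interval(0, 1),
#'   discount_factor = 0.95
#' )
#' evaluate_action(sc, gamma = 0.2)
#' @export
management_scenario <- function(pristine_profit, evolved_profit, persistence,
                                actions, rate = NULL, discount_factor = NULL,
                                gamma0 = NULL) {
  if (is.null(rate) && is.null(discount_factor)) {
    abort_validation("supply `rate` or `discount_factor`")
  }
  if (!is.null(rate)) check_number(rate, "rate", lower = 0)
  if (!is.null(discount_factor)) {
    check_number(discount_factor, "discount_factor", lower = 0, upper = 1,
                 strict_upper = TRUE)
  }
  if (!is.null(rate) && !is.null(discount_factor)) {
    if (!near(discount_factor, 1 / (1 + rate))) {
      abort_validation(
        "`rate` (%g) and `discount_factor` (%g) disagree: delta must equal 1/(1+r) = %g",
        rate, discount_factor, 1 / (1 + rate))
    }
  }
  delta <- if (is.null(discount_factor)) 1 / (1 + rate) else discount_factor
  r <- if (is.null(rate)) 1 / delta - 1 else rate

  Pi <- as_curve(pristine_profit, "pristine_profit")
  kappa <- as_curve(persistence, "persistence")
  check_number(evolved_profit, "evolved_profit")
  actions <- as_actions(actions)

  grid <- probe_actions(actions)
  kv <- kappa(grid)
  if (any(!is.finite(kv)) || any(kv < -.REL_TOL) || any(kv > 1 + .REL_TOL)) {
    abort_validation("persistence kappa(gamma) must lie in [0, 1] over the action set")
  }
  pv <- Pi(grid)
  if (any(!is.finite(pv))) {
    abort_validation("pristine_profit must be finite over the action set")
  }
  if (max(pv) <= evolved_profit) {
    abort_validation(
      "model assumption violated: max pristine profit (%g) must exceed evolved profit (%g)",
      max(pv), evolved_profit)
  }

  g0_hat <- argmax_profit(Pi, actions)
  if (is.null(gamma0)) {
    gamma0 <- g0_hat
  } else {
    check_number(gamma0, "gamma0")
    if (!action_in_set(gamma0, actions)) {
      abort_validation("pinned gamma0 = %g is not in the action set", gamma0)
    }
    if (!near(Pi(gamma0), Pi(g0_hat))) {
      warning(sprintf(
        "pinned gamma0 = %g does not maximize excess profit (argmax = %g); keeping the pinned value",
        gamma0, g0_hat), call. = FALSE)
    }
  }

  structure(
    list(rate = r, delta = delta, pristine_profit = Pi,
         evolved_profit = evolved_profit, persistence = kappa,
         actions = actions, gamma0 = gamma0),
    class = "management_scenario")
}

# argmax of Pi over the action set; ties broken toward smaller gamma
# (less stewardship), matching the strict-inequality convention.
argmax_profit <- function(Pi, actions, n = 1001L) {
  grid <- probe_actions(actions, n)
  v <- Pi(grid)
  best <- max(v)
  cand <- grid[v >= best - .REL_TOL * max(1, abs(best))]
  g <- min(cand)
  if (actions$type == "interval") {
    lo <- max(actions$bounds[1L], g - diff(actions$bounds) / (n - 1))
    hi <- min(actions$bounds[2L], g + diff(actions$bounds) / (n - 1))
    opt <- stats::optimize(Pi, c(lo, hi), maximum = TRUE, tol = 1e-10)
    if (opt$objective > best + .REL_TOL * max(1, abs(best))) g <- opt$maximum
  }
  g
}

#' @export
print.management_scenario <- function(x, ...) {
  cat("<management_scenario>\n")
  cat(sprintf("  discount: delta = %.6g (r = %.6g/yr)\n", x$delta, x$rate))
  cat(sprintf("  evolved-state profit: %.6g per year\n", x$evolved_profit))
  if (x$actions$type == "grid") {
    cat("  actions: grid {", paste(signif(x$actions$values, 6), collapse = ", "),
        "}\n")
  } else {
    cat(sprintf("  actions: interval [%g, %g]\n",
                x$actions$bounds[1L], x$actions$bounds[2L]))
  }
  cat(sprintf("  no-stewardship action gamma0 = %.6g\n", x$gamma0))
  invisible(x)
}

#' Effective life span of an excess-profit stream
#'
#' Combines economic discounting (`delta`, the time value of money) and
#' evolutionary discounting (`kappa`, the annual chance the excess stream
#' survives) into the multiplier `L = 1/(1 - delta * kappa)` that converts
#' one year's excess profit into the stream's total present value. `L`
#' always lies in `[1, 1/(1 - delta)]`.
#'
#' @param delta Annual discount factor in `[0, 1]`; `delta = 1` is allowed
#'   only with `kappa < 1`.
#' @param kappa Annual persistence probability in `[0, 1]`.
#' @return Effective life span in effective years.
#' @examples
#' effective_lifespan(0.9, 1)     # 10
#' effective_lifespan(0.95, 0.9210526)  # about 8
#' @export
effective_lifespan <- function(delta, kappa) {
  check_number(delta, "delta", lower = 0, upper = 1)
  check_number(kappa, "kappa", lower = 0, upper = 1)
  dk <- delta * kappa
  if (dk >= 1) {
    abort_validation(
      "non-finite lifespan: delta * kappa = 1 gives an undiscounted, never-ending stream")
  }
  1 / (1 - dk)
}

#' Annual excess profit of the pristine state
#'
#' `E(gamma) = Pi(gamma) - evolved_profit`: the profit earned per year
#' over and above the guaranteed evolved-state baseline, for as long as
#' the system stays pristine. May be negative for poor actions; such
#' actions are never beneficial.
#'
#' @param scenario A [management_scenario()].
#' @param gamma Action in the scenario's action set.
#' @return Excess profit per year.
#' @export
excess_profit <- function(scenario, gamma) {
  stopifnot(inherits(scenario, "management_scenario"))
  check_number(gamma, "gamma")
  if (!action_in_set(gamma, scenario$actions)) {
    abort_validation("gamma = %g is not in the scenario's action set", gamma)
  }
  scenario$pristine_profit(gamma) - scenario$evolved_profit
}

#' Present value of an excess-profit stream
#'
#' The total present value `E * L`, i.e. the closed form of the geometric
#' sum `E + (delta*kappa) E + (delta*kappa)^2 E + ...`.
#'
#' @param E Excess profit per year.
#' @param L Effective life span (`>= 1`), from [effective_lifespan()].
#' @return Present value (currency).
#' @export
stream_value <- function(E, L) {
  check_number(E, "E")
  check_number(L, "L", lower = 1)
  E * L
}

#' Evaluate the evolution management inequality for a candidate action
#'
#' Stewardship action `gamma` beats the no-stewardship choice `gamma0`
#' exactly when `E(gamma) L(gamma) > E(gamma0) L(gamma0)`, which in
#' dimensionless form reads
#' \deqn{\frac{L(\gamma)-L(\gamma_0)}{L(\gamma_0)} \;>\;
#'       \frac{E(\gamma_0)-E(\gamma)}{E(\gamma)}}
#' the percentage benefit `B` (gain in effective life span) against the
#' percentage cost `C` (annual excess profit forgone). The decision uses
#' the strict inequality; an exact tie is reported as not beneficial with
#' `tie = TRUE`.
#'
#' When `E(gamma) <= 0` the percentage-cost form is undefined (division by
#' a non-positive excess); the decision then falls back to the direct
#' present-value comparison and `percentage_form` is `FALSE`.
#'
#' @param scenario A [management_scenario()].
#' @param gamma Candidate stewardship action.
#' @param gamma0 Reference action; defaults to the scenario's
#'   no-stewardship action.
#' @return A `stewardship_evaluation`: a list with the action, `E`, `L`,
#'   present values `V` and `V0`, percentages `B` and `C`, and the flags
#'   `beneficial`, `tie`, `percentage_form`.
#' @export
evaluate_action <- function(scenario, gamma, gamma0 = NULL) {
  stopifnot(inherits(scenario, "management_scenario"))
  gamma0 <- gamma0 %||% scenario$gamma0
  for (g in c(gamma, gamma0)) {
    if (!action_in_set(g, scenario$actions)) {
      abort_validation("action %g is not in the scenario's action set", g)
    }
  }
  E <- scenario$pristine_profit(gamma) - scenario$evolved_profit
  E0 <- scenario$pristine_profit(gamma0) - scenario$evolved_profit
  L <- effective_lifespan(scenario$delta, scenario$persistence(gamma))
  L0 <- effective_lifespan(scenario$delta, scenario$persistence(gamma0))
  V <- E * L
  V0 <- E0 * L0

  tie <- near(V, V0)
  if (E > 0) {
    B <- (L - L0) / L0
    C <- (E0 - E) / E
    beneficial <- !tie && B > C
    pct <- TRUE
  } else {
    B <- NA_real_
    C <- NA_real_
    beneficial <- !tie && V > V0
    pct <- FALSE
  }
  structure(
    list(gamma = gamma, gamma0 = gamma0, E = E, E0 = E0, L = L, L0 = L0,
         V = V, V0 = V0, benefit_pct = B, cost_pct = C,
         beneficial = beneficial, tie = tie, percentage_form = pct),
    class = "stewardship_evaluation")
}

#' @export
print.stewardship_evaluation <- function(x, ...) {
  cat("<stewardship_evaluation>\n")
  cat(sprintf("  action gamma = %.6g (vs gamma0 = %.6g)\n", x$gamma, x$gamma0))
  cat(sprintf("  excess profit E = %.6g/yr, effective life span L = %.6g\n",
              x$E, x$L))
  cat(sprintf("  present value V = %.6g (vs V0 = %.6g)\n", x$V, x$V0))
  if (x$percentage_form) {
    cat(sprintf("  benefit B = %.4g%%, cost C = %.4g%%\n",
                100 * x$benefit_pct, 100 * x$cost_pct))
  } else {
    cat("  percentage form undefined (E <= 0); direct value comparison used\n")
  }
  cat(sprintf("  beneficial: %s%s\n", x$beneficial,
              if (x$tie) " (exact tie)" else ""))
  invisible(x)
}

#' Expanded form of the evolution management inequality
#'
#' The same decision written directly in model primitives:
#' \deqn{\frac{\delta(\kappa(\gamma)-\kappa(\gamma_0))}{1-\delta\kappa(\gamma)}
#'       \;>\; \frac{\Pi(\gamma_0)-\Pi(\gamma)}{\Pi(\gamma)-\bar\Pi}}
#' Useful for comparative statics: the left side vanishes when discounting
#' is complete (`delta = 0`) or when the action does not slow evolution
#' (`kappa_gamma = kappa_gamma0`), so costly stewardship can never pay in
#' either case.
#'
#' @param delta Annual discount factor in `[0, 1)`.
#' @param kappa_gamma,kappa_gamma0 Persistence under stewardship and under
#'   no stewardship.
#' @param pi_gamma,pi_gamma0 Pristine annual profits of the two actions.
#' @param pi_bar Evolved-state annual profit; requires `pi_gamma > pi_bar`.
#' @return List with `lhs`, `rhs`, `beneficial`, `tie`.
#' @export
evaluate_action_expanded <- function(delta, kappa_gamma, kappa_gamma0,
                                     pi_gamma, pi_gamma0, pi_bar) {
  check_number(delta, "delta", lower = 0, upper = 1, strict_upper = TRUE)
  check_number(kappa_gamma, "kappa_gamma", lower = 0, upper = 1)
  check_number(kappa_gamma0, "kappa_gamma0", lower = 0, upper = 1)
  check_number(pi_gamma, "pi_gamma")
  check_number(pi_gamma0, "pi_gamma0")
  check_number(pi_bar, "pi_bar")
  if (pi_gamma <= pi_bar) {
    abort_validation(
      "expanded form requires pristine profit under gamma (%g) above evolved profit (%g)",
      pi_gamma, pi_bar)
  }
  lhs <- delta * (kappa_gamma - kappa_gamma0) / (1 - delta * kappa_gamma)
  rhs <- (pi_gamma0 - pi_gamma) / (pi_gamma - pi_bar)
  tie <- near(lhs, rhs)
  list(lhs = lhs, rhs = rhs, beneficial = !tie && lhs > rhs, tie = tie)
}
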