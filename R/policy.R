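#' Apply a permanent per-year stewardship subsidy
#'
#' Paying `S` per year to managers while they steward (and the system is
#' pristine) raises the steward's annual excess profit from `E_p(g)` to
#' `E_p(g) + S`, which lowers the percentage cost curve to
#' `C_S(p) = (E_p(g0) - E_p(g) - S) / (E_p(g) + S)` for every `p` while
#' leaving the benefit curve untouched. `mode = "net_cost"` instead
#' treats the subsidy as a flat rebate that does not enter the cost base:
#' `C_S(p) = (E_p(g0) - E_p(g) - S) / E_p(g)`.
#'
#' @param game A [population_game()].
#' @param S Subsidy per stewarding year, `>= 0`.
#' @param mode `"stewarding"` (default: subsidy is part of the steward's
#'   excess profit) or `"net_cost"` (flat rebate).
#' @return The subsidized [population_game()].
#' @export
apply_permanent_subsidy <- function(game, S, mode = c("stewarding", "net_cost")) {
  stopifnot(inherits(game, "population_game"))
  check_number(S, "S", lower = 0)
  mode <- match.arg(mode)
  if (S == 0) return(game)
  Eg <- game$excess_steward
  Eg0 <- game$excess_nosteward
  if (mode == "stewarding") {
    new_Eg <- structure(function(p) Eg(p) + S,
                        class = c("parametric_fn", "function"),
                        family = "custom", params = NULL)
    new_Eg0 <- Eg0
  } else {
    # Flat rebate: lower the no-steward side instead so the denominator
    # (the steward's own excess) is unchanged.
    new_Eg <- Eg
    new_Eg0 <- structure(function(p) Eg0(p) - S,
                         class = c("parametric_fn", "function"),
                         family = "custom", params = NULL)
  }
  out <- game
  out$excess_steward <- new_Eg
  out$excess_nosteward <- new_Eg0
  out$description <- paste0(game$description %||% "game",
                            sprintf(" + subsidy S=%g (%s)", S, mode))
  out
}

#' Smallest subsidy that makes stewardship dominant
#'
#' Finds the smallest per-year subsidy `S*` such that stewardship is
#' beneficial for every manager regardless of what others do, i.e.
#' `B(p) > C_S(p)` for all `p`. Solving `B(p) = C_S(p)` for `S`
#' pointwise gives
#' `S(p) = (E_p(g0) - E_p(g) - B(p) E_p(g)) / (1 + B(p))`,
#' and `S* = max(0, max_p S(p))` over the grid.
#'
#' @param game A [population_game()].
#' @param p_grid Grid on which dominance is enforced.
#' @return List with `S_star` and `binding_p` (the grid point that
#'   requires the largest subsidy).
#' @export
minimum_switching_subsidy <- function(game, p_grid = seq(0, 1, length.out = 1001)) {
  stopifnot(inherits(game, "population_game"))
  bc <- benefit_cost_curves(game, p_grid)
  if (any(bc$B <= -1)) {
    abort_validation(
      "degenerate game: benefit curve at or below -100%% (B <= -1) at p = %g",
      p_grid[which(bc$B <= -1)[1L]])
  }
  Eg <- game$excess_steward(p_grid)
  Eg0 <- game$excess_nosteward(p_grid)
  S_p <- (Eg0 - Eg - bc$B * Eg) / (1 + bc$B)
  i <- which.max(S_p)
  list(S_star = max(0, S_p[i]), binding_p = p_grid[i])
}

#' Outcome of a one-year ("temporary") subsidy
#'
#' The regulator pays `S` per stewarding manager for a single year; from
#' the next year on the game reverts to its unsubsidized form. During the
#' subsidized year the population adjusts under the subsidized incentives
#' (with `S >=` [minimum_switching_subsidy()] stewardship is dominant and
#' the population moves to `p = 1`); afterwards, best-response dynamics
#' run on the original game from wherever the subsidy left the
#' population. Under negative strategic feedback the population drifts
#' back to the unique equilibrium — no lasting effect; under positive
#' feedback a large enough subsidy tips the population into the basin of
#' the all-stewardship equilibrium — a permanent regime switch.
#'
#' @param game A [population_game()].
#' @param S Subsidy per stewarding year during the intervention year.
#' @param p_init Stewarding fraction before the intervention.
#' @param ... Passed to [best_response_dynamics()].
#' @return A `policy_outcome`: equilibrium sets before and under the
#'   subsidy, `p_after_subsidy`, `long_run_p`, the no-subsidy baseline
#'   limit, `delta_p`, and a `narrative_class` of `"no_effect"`,
#'   `"marginal_shift"`, or `"regime_switch"`.
#' @export
temporary_subsidy_outcome <- function(game, S, p_init, ...) {
  stopifnot(inherits(game, "population_game"))
  check_number(S, "S", lower = 0)
  check_number(p_init, "p_init", lower = 0, upper = 1)

  pre <- find_nash_equilibria(game)
  sub_game <- apply_permanent_subsidy(game, S)
  post <- find_nash_equilibria(sub_game)

  baseline <- best_response_dynamics(game, p_init, ...)$limit
  p_after <- if (S > 0) {
    best_response_dynamics(sub_game, p_init, ...)$limit
  } else {
    p_init
  }
  long_run <- best_response_dynamics(game, p_after, ...)$limit

  delta_p <- long_run - baseline
  narrative <- classify_policy_outcome(pre, baseline, long_run)
  structure(
    list(pre_equilibria = pre, post_equilibria = post,
         p_after_subsidy = p_after, long_run_p = long_run,
         baseline_p = baseline, delta_p = delta_p,
         narrative_class = narrative),
    class = "policy_outcome")
}

# "regime_switch" only when the population ends at a *different*
# pre-intervention stable equilibrium than it started from; a moved
# equilibrium (permanent subsidy under negative feedback) is a
# marginal shift.
classify_policy_outcome <- function(pre, baseline, long_run, tol = 1e-4) {
  if (abs(long_run - baseline) <= 1e-6) return("no_effect")
  stable <- pre$equilibria$p_star[pre$equilibria$stability == "stable"]
  nearest <- function(p) {
    if (!length(stable)) return(NA_real_)
    d <- abs(stable - p)
    if (min(d) <= tol) stable[which.min(d)] else NA_real_
  }
  pb <- nearest(baseline)
  pl <- nearest(long_run)
  if (!is.na(pb) && !is.na(pl) && abs(pb - pl) > tol) "regime_switch"
  else "marginal_shift"
}

#' Outcome of a permanent subsidy
#'
#' Compares the stable equilibria of the game before and after a
#' permanent per-year subsidy. Under negative feedback a small subsidy
#' nudges the unique stable equilibrium up slightly; under positive
#' feedback a subsidy below the switching threshold leaves the
#' no-stewardship equilibrium intact.
#'
#' @inheritParams temporary_subsidy_outcome
#' @return A `policy_outcome` where `long_run_p` is the limit of dynamics
#'   under the subsidized game from `p_init`.
#' @export
permanent_subsidy_outcome <- function(game, S, p_init, ...) {
  stopifnot(inherits(game, "population_game"))
  check_number(S, "S", lower = 0)
  check_number(p_init, "p_init", lower = 0, upper = 1)
  pre <- find_nash_equilibria(game)
  sub_game <- apply_permanent_subsidy(game, S)
  post <- find_nash_equilibria(sub_game)
  baseline <- best_response_dynamics(game, p_init, ...)$limit
  long_run <- best_response_dynamics(sub_game, p_init, ...)$limit
  delta_p <- long_run - baseline
  narrative <- classify_policy_outcome(pre, baseline, long_run)
  structure(
    list(pre_equilibria = pre, post_equilibria = post,
         p_after_subsidy = long_run, long_run_p = long_run,
         baseline_p = baseline, delta_p = delta_p,
         narrative_class = narrative),
    class = "policy_outcome")
}

#' @export
print.policy_outcome <- function(x, ...) {
  cat("<policy_outcome>\n")
  cat(sprintf("  baseline p = %.6g -> long-run p = %.6g (delta %.3g)\n",
              x$baseline_p, x$long_run_p, x$delta_p))
  cat(sprintf("  classification: %s\n", x$narrative_class))
  invisible(x)
}

#' Collective (cartel) optimum of a population game
#'
#' A cartel that can dictate the stewarding fraction maximizes the
#' per-manager expected present value
#' `W(p) = p * E_p(g) L_p(g) + (1 - p) * E_p(g0) L_p(g0)` instead of
#' letting each manager best-respond. When stewardship exerts a positive
#' externality (`d(E_p(g) L_p(g))/dp > 0`) the cartel stewards more than
#' the Nash equilibrium would.
#'
#' @param game A [population_game()].
#' @param grid_n Grid size for the initial scan; the best point is
#'   refined by golden-section search in its bracket.
#' @return List with `p_cartel`, `W_cartel`, the stable Nash points
#'   `p_nash` with their `W_nash`, and the nonnegative `gap`
#'   `W_cartel - max(W_nash)` (`NA` if no stable Nash point exists).
#' @export
collective_optimum <- function(game, grid_n = 1001L) {
  stopifnot(inherits(game, "population_game"))
  W <- function(p) {
    p * game$excess_steward(p) * game$lifespan_steward(p) +
      (1 - p) * game$excess_nosteward(p) * game$lifespan_nosteward(p)
  }
  grid <- seq(0, 1, length.out = grid_n)
  wv <- W(grid)
  i <- which.max(wv)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(grid_n, i + 1L)]
  opt <- stats::optimize(W, c(lo, hi), maximum = TRUE, tol = 1e-10)
  p_cartel <- if (opt$objective > wv[i]) opt$maximum else grid[i]
  W_cartel <- max(opt$objective, wv[i])

  eq <- find_nash_equilibria(game)$equilibria
  stable <- eq$p_star[eq$stability == "stable"]
  W_nash <- if (length(stable)) W(stable) else numeric(0)
  gap <- if (length(stable)) W_cartel - max(W_nash) else NA_real_
  list(p_cartel = p_cartel, W_cartel = W_cartel,
       p_nash = stable, W_nash = W_nash, gap = gap)
}

#' Sign of the stewardship externality
#'
#' Finite-difference estimate of `d(E_p L_p)/dp` for the chosen action: a
#' positive derivative means one manager's stewardship raises the others'
#' present values (a positive externality, the precondition for cartels
#' and subsidies to raise collective profit). Central differences with
#' step `h` are used in the interior; at the boundaries a one-sided
#' difference is used and flagged.
#'
#' @param game A [population_game()].
#' @param action `"steward"` or `"nosteward"`.
#' @param p Evaluation point in `[0, 1]`.
#' @param h Finite-difference step.
#' @return List with `derivative`, `sign` (`-1`, `0`, `1`, zero band
#'   1e-9), and `one_sided`.
#' @export
externality_sign <- function(game, action = c("steward", "nosteward"),
                             p, h = 1e-5) {
  stopifnot(inherits(game, "population_game"))
  action <- match.arg(action)
  check_number(p, "p", lower = 0, upper = 1)
  check_number(h, "h", lower = 0, strict_lower = TRUE)
  f <- if (action == "steward") {
    function(q) game$excess_steward(q) * game$lifespan_steward(q)
  } else {
    function(q) game$excess_nosteward(q) * game$lifespan_nosteward(q)
  }
  one_sided <- FALSE
  if (p - h < 0) {
    d <- (f(p + h) - f(p)) / h
    one_sided <- TRUE
  } else if (p + h > 1) {
    d <- (f(p) - f(p - h)) / h
    one_sided <- TRUE
  } else {
    d <- (f(p + h) - f(p - h)) / (2 * h)
  }
  s <- if (abs(d) <= 1e-9) 0 else sign(d)
  list(derivative = d, sign = s, one_sided = one_sided)
}
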