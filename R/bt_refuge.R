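#' Percentage cost of a Bt refuge
#'
#' A farmer planting fraction `gamma` of the land with non-Bt crops
#' forgoes the Bt yield advantage on that fraction. When the farmer would
#' keep planting non-Bt corn after resistance spreads, the per-acre costs
#' and revenues cancel and the percentage cost of the refuge reduces to
#' `gamma / (1 - gamma)` — independent of prices. A 20% refuge therefore
#' costs 25% of annual excess profit.
#'
#' @param gamma Refuge fraction in `[0, 1)`.
#' @return Dimensionless percentage cost (as a proportion, e.g. 0.25).
#' @examples
#' refuge_cost_percentage(0.2)   # 0.25
#' refuge_cost_percentage(0.26)  # about 0.351
#' @export
refuge_cost_percentage <- function(gamma) {
  check_number(gamma, "gamma", lower = 0, upper = 1, strict_upper = TRUE)
  if (near(gamma, 1)) {
    abort_validation("gamma = 1 plants no Bt at all: infinite percentage cost")
  }
  gamma / (1 - gamma)
}

#' Minimum effective-life-span gain for a refuge to pay
#'
#' With baseline resistance-free effective life span `L0` (no refuge), a
#' refuge of fraction `gamma` is economically beneficial only if it
#' extends the effective life span by at least `L0 * gamma / (1 - gamma)`
#' effective years. At `L0 = 8` and `gamma = 0.2` the requirement is 2
#' effective years.
#'
#' @param L0 Baseline effective life span (`>= 1` effective years).
#' @param gamma Refuge fraction in `[0, 1)`.
#' @return Required gain in effective years.
#' @export
required_lifespan_gain <- function(L0, gamma) {
  check_number(L0, "L0", lower = 1)
  L0 * refuge_cost_percentage(gamma)
}

#' Minimum calendar life span for a refuge to pay
#'
#' Finite-horizon version of the refuge decision: efficacy is treated as
#' lasting a deterministic `T` calendar years (full persistence, then a
#' certain regime shift), so the effective life span of a `T`-year stream
#' is `L_fin(T) = (1 - delta^T) / (1 - delta)` with `delta = 1/(1 + r)`.
#' A refuge of fraction `gamma` that stretches efficacy from `N` to `M`
#' calendar years is beneficial when `L_fin(M) / L_fin(N) >= 1/(1 -
#' gamma)`; this function returns the smallest such `M`.
#'
#' Because `L_fin` is bounded by `1/(1 - delta)`, no finite `M` suffices
#' when `delta^N <= gamma`; that case is reported as infeasible rather
#' than raised as an error.
#'
#' @param N Baseline calendar life span in years (`>= 1`).
#' @param gamma Refuge fraction in `[0, 1)`.
#' @param r Annual interest rate (`> 0`).
#' @return A `calendar_lifespan` list: `feasible`, the real-valued
#'   threshold `M_real`, and the integer `M_years` (the smallest whole
#'   number of years that satisfies the inequality).
#' @examples
#' min_calendar_lifespan(N = 15, gamma = 0.26, r = 0.04)  # about 23.4
#' @export
min_calendar_lifespan <- function(N, gamma, r) {
  check_number(N, "N", lower = 1)
  check_number(gamma, "gamma", lower = 0, upper = 1, strict_upper = TRUE)
  check_number(r, "r", lower = 0, strict_lower = TRUE)
  delta <- 1 / (1 + r)

  if (gamma == 0) {
    return(structure(list(feasible = TRUE, M_real = N, M_years = ceiling(N)),
                     class = "calendar_lifespan"))
  }
  # need 1 - delta^M >= (1 - delta^N) / (1 - gamma)
  target <- (1 - delta^N) / (1 - gamma)
  if (target >= 1) {
    return(structure(
      list(feasible = FALSE, M_real = Inf, M_years = Inf),
      class = "calendar_lifespan"))
  }
  M_real <- log(1 - target) / log(delta)
  M_years <- ceiling(M_real - .REL_TOL * M_real)
  structure(list(feasible = TRUE, M_real = M_real, M_years = M_years),
            class = "calendar_lifespan")
}

#' @export
print.calendar_lifespan <- function(x, ...) {
  if (x$feasible) {
    cat(sprintf(
      "smallest calendar life span: %.4g years (next whole year: %d)\n",
      x$M_real, as.integer(x$M_years)))
  } else {
    cat("no finite calendar life span satisfies the inequality\n")
  }
  invisible(x)
}

# Finite-horizon effective life span of a T-year stream.
finite_lifespan <- function(T, delta) {
  if (delta == 1) T else (1 - delta^T) / (1 - delta)
}

#' Refuge cost with a profitable outside option after resistance
#'
#' The price-free `gamma/(1 - gamma)` cost assumes the farmer keeps
#' growing (non-Bt) corn after resistance spreads. If instead the land
#' has a better post-resistance use worth `pi_alt` per acre per year, the
#' percentage cost of the refuge becomes
#' `(pi_bt - ((1-gamma) pi_bt + gamma pi_non)) /
#'  (((1-gamma) pi_bt + gamma pi_non) - pi_alt)`,
#' which reduces to `gamma/(1 - gamma)` at `pi_alt = pi_non` and grows
#' without bound as the outside option approaches the pristine mixed
#' profit — a richer fallback weakens the case for stewardship.
#'
#' @param gamma Refuge fraction in `[0, 1)`.
#' @param pi_bt Per-acre pristine profit of Bt planting.
#' @param pi_non Per-acre pristine profit of non-Bt planting.
#' @param pi_alt Per-acre annual profit of the post-resistance outside
#'   option; requires `pi_bt > pi_alt`.
#' @return List with the percentage `cost` (possibly `Inf`) and the flag
#'   `never_beneficial` (excess profit non-positive under the refuge).
#' @examples
#' alternative_landuse_cost(0.2, 100, 60, 60)$cost  # 0.25
#' alternative_landuse_cost(0.2, 100, 60, 70)$cost  # about 0.364
#' @export
alternative_landuse_cost <- function(gamma, pi_bt, pi_non, pi_alt) {
  check_number(gamma, "gamma", lower = 0, upper = 1, strict_upper = TRUE)
  check_number(pi_bt, "pi_bt")
  check_number(pi_non, "pi_non")
  check_number(pi_alt, "pi_alt")
  if (pi_bt <= pi_alt) {
    abort_validation(
      "pristine Bt profit (%g) must exceed the outside option (%g)",
      pi_bt, pi_alt)
  }
  mixed <- (1 - gamma) * pi_bt + gamma * pi_non
  num <- pi_bt - mixed
  den <- mixed - pi_alt
  if (den <= 0) {
    return(list(cost = Inf, never_beneficial = TRUE))
  }
  list(cost = num / den, never_beneficial = FALSE)
}
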