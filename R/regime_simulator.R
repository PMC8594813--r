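#' Sample the year in which adverse evolution occurs
#'
#' Under annual persistence probability `kappa`, the regime shift arrives
#' in year `t` with probability `kappa^(t-1) * (1 - kappa)`: a geometric
#' law on `{1, 2, ...}` with mean `1/(1 - kappa)`. With `kappa = 1` the
#' shift never happens and every draw is `Inf` (a sentinel, not an error).
#'
#' @param kappa Annual persistence probability in `[0, 1]`.
#' @param reps Number of draws.
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#' @return Integer-valued numeric vector of shift years (`Inf` if never).
#' @examples
#' mean(sample_evolution_time(0.9, 1e4, seed = 1))  # near 10
#' @export
sample_evolution_time <- function(kappa, reps, seed = NULL) {
  check_number(kappa, "kappa", lower = 0, upper = 1)
  check_number(reps, "reps", lower = 1)
  reps <- as.integer(reps)
  if (kappa == 1) return(rep(Inf, reps))
  with_seed(seed, 1 + stats::rgeom(reps, prob = 1 - kappa))
}

# Truncation horizon: smallest T with (delta*kappa)^T / (1 - delta*kappa)
# below `tol` relative to the stream value, so the neglected tail cannot
# move the reported mean.
default_horizon <- function(delta, kappa, tol = 1e-10) {
  dk <- delta * kappa
  if (dk <= 0) return(1L)
  if (dk >= 1) abort_validation("non-finite lifespan: delta * kappa = 1")
  as.integer(ceiling(log(tol * (1 - dk)) / log(dk))) + 1L
}

new_simulation_result <- function(pv_samples, shift_times, horizon, seed,
                                  reps, analytic_pv) {
  structure(
    list(pv_samples = pv_samples,
         mean_pv = mean(pv_samples),
         std_error = stats::sd(pv_samples) / sqrt(length(pv_samples)),
         shift_times = shift_times,
         horizon = horizon, seed = seed, reps = reps,
         analytic_pv = analytic_pv),
    class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("<simulation_result>\n")
  cat(sprintf("  reps = %d, horizon = %d years, seed = %s\n",
              x$reps, x$horizon, if (is.null(x$seed)) "none" else x$seed))
  cat(sprintf("  mean PV = %.6g (std error %.3g); analytic PV = %.6g\n",
              x$mean_pv, x$std_error, x$analytic_pv))
  cat(sprintf("  shifted within horizon: %d / %d replicates\n",
              sum(is.finite(x$shift_times)), x$reps))
  invisible(x)
}

#' Monte Carlo valuation of the pristine-state excess-profit stream
#'
#' Each replicate earns the annual excess profit `E(gamma)` discounted by
#' `delta^(t-1)` for years `t = 1, ..., T` where `T` is a geometric shift
#' time drawn with persistence `kappa(gamma)` (profit accrues at the start
#' of the year; evolution is checked at year end, so the first year is
#' always earned). The replicate mean estimates the analytic present
#' value `E(gamma) * L(gamma)`, which is returned alongside for
#' comparison.
#'
#' @param scenario A [management_scenario()].
#' @param gamma Action to simulate.
#' @param reps Number of replicates.
#' @param horizon Truncation horizon in years; defaults to the smallest
#'   horizon with relative truncation bias below `1e-10`. A horizon too
#'   small for that precision triggers a warning with the bias bound.
#' @param seed Optional integer seed.
#' @return A `simulation_result` with fields `pv_samples`, `mean_pv`,
#'   `std_error`, `shift_times` (`Inf` when censored at the horizon),
#'   `horizon`, `seed`, `reps`, `analytic_pv`.
#' @export
simulate_pristine_stream <- function(scenario, gamma, reps = 10000,
                                     horizon = NULL, seed = NULL) {
  stopifnot(inherits(scenario, "management_scenario"))
  E <- excess_profit(scenario, gamma)
  kappa <- scenario$persistence(gamma)
  delta <- scenario$delta
  if (delta * kappa >= 1) {
    abort_validation("non-finite stream: delta * kappa(gamma) = 1")
  }
  want <- default_horizon(delta, kappa)
  horizon <- if (is.null(horizon)) want else as.integer(horizon)
  if (horizon < want) {
    dk <- delta * kappa
    warning(sprintf(
      "horizon %d leaves relative truncation bias %.3g (about %.3g currency units)",
      horizon, dk^horizon, dk^horizon / (1 - dk) * abs(E)), call. = FALSE)
  }
  reps <- as.integer(check_number(reps, "reps", lower = 1))

  shift <- sample_evolution_time(kappa, reps, seed)
  years <- pmin(shift, horizon)
  pv <- if (delta == 1) E * years else E * (1 - delta^years) / (1 - delta)
  analytic <- E * effective_lifespan(delta, kappa)
  shift[shift > horizon] <- Inf
  new_simulation_result(pv, shift, horizon, seed, reps, analytic)
}

#' Exact present value under reversible evolution
#'
#' When the evolved state can revert to pristine with annual probability
#' `rho`, the expected discounted excess profit starting pristine solves
#' the linear system
#' `Vp = E + delta * (kappa * Vp + (1 - kappa) * Ve)`,
#' `Ve = delta * (rho * Vp + (1 - rho) * Ve)`
#' (only excess profit is earned, and only in the pristine state; the
#' evolved state pays the baseline). `rho = 0` recovers the irreversible
#' stream value `E * L`.
#'
#' @param E Annual excess profit in the pristine state.
#' @param delta Discount factor in `[0, 1)`.
#' @param kappa Annual persistence probability.
#' @param rho Annual reversal probability.
#' @return Expected present value started in the pristine state.
#' @export
reversible_stream_value <- function(E, delta, kappa, rho) {
  check_number(E, "E")
  check_number(delta, "delta", lower = 0, upper = 1, strict_upper = TRUE)
  check_number(kappa, "kappa", lower = 0, upper = 1)
  check_number(rho, "rho", lower = 0, upper = 1)
  A <- rbind(c(1 - delta * kappa, -delta * (1 - kappa)),
             c(-delta * rho, 1 - delta * (1 - rho)))
  drop(solve(A, c(E, 0)))[1L]
}

#' Monte Carlo valuation under reversible evolution
#'
#' Simulates the two-state Markov chain pristine -> evolved (probability
#' `1 - kappa(gamma)` per year) and evolved -> pristine (probability
#' `rho`), accruing discounted excess profit in pristine years only, and
#' compares the replicate mean with the exact linear-system value from
#' [reversible_stream_value()]. `rho = 0` reduces to
#' [simulate_pristine_stream()] up to sampling error.
#'
#' @inheritParams simulate_pristine_stream
#' @param rho Annual probability that the evolved state reverts to
#'   pristine.
#' @return A `simulation_result`; `shift_times` records the first shift
#'   year of each replicate (`Inf` if none within the horizon).
#' @export
simulate_reversible <- function(scenario, gamma, rho, reps = 10000,
                                horizon = NULL, seed = NULL) {
  stopifnot(inherits(scenario, "management_scenario"))
  check_number(rho, "rho", lower = 0, upper = 1)
  E <- excess_profit(scenario, gamma)
  kappa <- scenario$persistence(gamma)
  delta <- scenario$delta
  if (delta >= 1) abort_validation("reversible simulation requires delta < 1")
  # With reversal the excess stream never hard-stops, so the horizon must
  # damp delta itself, not delta * kappa.
  horizon <- if (is.null(horizon)) default_horizon(delta, 1 - 1e-12)
             else as.integer(horizon)
  reps <- as.integer(check_number(reps, "reps", lower = 1))

  with_seed(seed, {
    pristine <- rep(TRUE, reps)
    pv <- numeric(reps)
    first_shift <- rep(Inf, reps)
    disc <- 1
    for (t in seq_len(horizon)) {
      pv <- pv + disc * E * pristine
      u <- stats::runif(reps)
      shifting <- pristine & (u > kappa)
      reverting <- !pristine & (u < rho)
      first_shift[shifting] <- pmin(first_shift[shifting], t)
      pristine <- (pristine & !shifting) | reverting
      disc <- disc * delta
    }
    analytic <- reversible_stream_value(E, delta, kappa, rho)
    new_simulation_result(pv, first_shift, horizon, seed, reps, analytic)
  })
}
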