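#' Define a population game of interacting managers
#'
#' Many identical managers each choose between a fixed stewardship level
#' and no stewardship. Both the annual excess profit `E` and the
#' effective life span `L` of each choice may depend on the fraction
#' `p` of managers who steward (neighbors' refuges change pest pressure,
#' other hospitals' stewardship changes community resistance, ...). The
#' game is specified by the four `p`-indexed curves
#' `E_p(steward)`, `E_p(no steward)`, `L_p(steward)`, `L_p(no steward)`,
#' from which the percentage benefit and cost of stewardship are
#' `B(p) = (L_p(g) - L_p(g0)) / L_p(g0)` and
#' `C(p) = (E_p(g0) - E_p(g)) / E_p(g)`; an individual stewards when
#' `B(p) > C(p)`.
#'
#' @param excess_steward,excess_nosteward Annual excess profit of the two
#'   choices as functions of `p` ([parametric_fn()], plain function, or a
#'   number). `excess_steward` must be strictly positive on `[0, 1]` so
#'   the percentage cost is defined.
#' @param lifespan_steward,lifespan_nosteward Effective life spans of the
#'   two choices as functions of `p`; must be `>= 1` on `[0, 1]`.
#' @param description Optional label carried along for printing.
#' @return An object of class `population_game`.
#' @examples
#' g <- population_game(
#'   excess_steward    = 1,
#'   excess_nosteward  = parametric_fn("linear", list(intercept = 1.2, slope = 0.2)),
#'   lifespan_steward  = parametric_fn("linear", list(intercept = 7.5, slope = -1.5)),
#'   lifespan_nosteward = 5
#' )
#' find_nash_equilibria(g)
#' @export
population_game <- function(excess_steward, excess_nosteward,
                            lifespan_steward, lifespan_nosteward,
                            description = NULL) {
  Eg <- as_curve(excess_steward, "excess_steward")
  Eg0 <- as_curve(excess_nosteward, "excess_nosteward")
  Lg <- as_curve(lifespan_steward, "lifespan_steward")
  Lg0 <- as_curve(lifespan_nosteward, "lifespan_nosteward")

  probe <- seq(0, 1, length.out = 201)
  if (any(Eg(probe) <= 0)) {
    abort_validation(
      "excess_steward must be strictly positive on [0, 1] (percentage cost is a ratio to it)")
  }
  for (nm in c("lifespan_steward", "lifespan_nosteward")) {
    f <- if (nm == "lifespan_steward") Lg else Lg0
    if (any(f(probe) < 1 - .REL_TOL)) {
      abort_validation("`%s` must be >= 1 on [0, 1]", nm)
    }
  }
  structure(
    list(excess_steward = Eg, excess_nosteward = Eg0,
         lifespan_steward = Lg, lifespan_nosteward = Lg0,
         description = description),
    class = "population_game")
}

#' @export
print.population_game <- function(x, ...) {
  cat("<population_game>")
  if (!is.null(x$description)) cat(" ", x$description)
  cat("\n")
  bc <- benefit_cost_curves(x, c(0, 0.5, 1))
  cat(sprintf("  B(p): %.4g at p=0, %.4g at p=0.5, %.4g at p=1\n",
              bc$B[1L], bc$B[2L], bc$B[3L]))
  cat(sprintf("  C(p): %.4g at p=0, %.4g at p=0.5, %.4g at p=1\n",
              bc$C[1L], bc$C[2L], bc$C[3L]))
  invisible(x)
}

#' Percentage benefit and cost curves of a population game
#'
#' @param game A [population_game()].
#' @param p_grid Fractions of stewarding managers at which to evaluate;
#'   must lie in `[0, 1]`.
#' @return A tibble with columns `p`, `B`, `C`, `gap` (`= B - C`).
#' @export
benefit_cost_curves <- function(game, p_grid = seq(0, 1, by = 0.01)) {
  stopifnot(inherits(game, "population_game"))
  if (any(p_grid < -.REL_TOL | p_grid > 1 + .REL_TOL)) {
    abort_validation("p_grid must lie in [0, 1]")
  }
  Eg <- game$excess_steward(p_grid)
  if (any(Eg <= 0)) {
    abort_validation("excess_steward is non-positive at p = %g",
                     p_grid[which(Eg <= 0)[1L]])
  }
  Eg0 <- game$excess_nosteward(p_grid)
  Lg <- game$lifespan_steward(p_grid)
  Lg0 <- game$lifespan_nosteward(p_grid)
  B <- (Lg - Lg0) / Lg0
  C <- (Eg0 - Eg) / Eg
  tibble::tibble(p = p_grid, B = B, C = C, gap = B - C)
}

game_gap_fn <- function(game) {
  function(p) {
    Eg <- game$excess_steward(p)
    (game$lifespan_steward(p) - game$lifespan_nosteward(p)) /
      game$lifespan_nosteward(p) -
      (game$excess_nosteward(p) - Eg) / Eg
  }
}

#' Nash equilibria and convergence stability
#'
#' A fraction `p*` is a Nash equilibrium of the binary stewardship game
#' when no manager gains by unilaterally switching: interior points where
#' the benefit and cost curves cross (`B(p*) = C(p*)`), the boundary
#' `p = 0` when stewardship does not pay there (`B(0) <= C(0)`), and
#' `p = 1` when it does (`B(1) >= C(1)`). Convergence stability is read
#' off the sign of `g(p) = B(p) - C(p)` around each point: an interior
#' crossing from positive to negative attracts best-response adjustment
#' (stable); `p = 0` is stable when `g(0) < 0` and `p = 1` when
#' `g(1) > 0`. A crossing the gap merely touches (no sign change) is
#' labelled `"marginal"` and not counted as stable.
#'
#' Interior crossings are located by a sign-change scan at
#' `scan_resolution` followed by bisection to `tol`. If the gap is
#' numerically zero over a stretch of the scan grid, that stretch is
#' reported as a continuum of equilibria instead of isolated points.
#'
#' @param game A [population_game()].
#' @param scan_resolution Spacing of the sign-change scan (default 1e-3).
#' @param tol Bisection tolerance on `p` (default 1e-10).
#' @return An `equilibrium_set`: tibble `equilibria` (columns `p_star`,
#'   `kind` = interior/boundary, `stability` = stable/unstable/marginal),
#'   `feedback_class`, `gap_samples`, and `continua` (list of flat
#'   intervals, usually empty).
#' @export
find_nash_equilibria <- function(game, scan_resolution = 1e-3, tol = 1e-10) {
  stopifnot(inherits(game, "population_game"))
  g <- game_gap_fn(game)
  grid <- seq(0, 1, by = scan_resolution)
  gv <- g(grid)
  if (any(!is.finite(gv))) {
    abort_validation("benefit/cost gap is non-finite on the scan grid")
  }
  flat_tol <- .REL_TOL * max(1, max(abs(gv)))
  is_flat <- abs(gv) <= flat_tol

  # Runs of >= 3 consecutive numerically-zero grid points: a continuum.
  continua <- list()
  r <- rle(is_flat)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (r$values[i] && r$lengths[i] >= 3L) {
      continua[[length(continua) + 1L]] <- c(grid[starts[i]], grid[ends[i]])
    }
  }
  in_continuum <- function(p) {
    any(vapply(continua, function(iv) p >= iv[1L] - scan_resolution &&
                 p <= iv[2L] + scan_resolution, logical(1)))
  }

  p_star <- numeric(0)
  kind <- character(0)
  stability <- character(0)

  # Walk consecutive pairs of non-flat grid points. Opposite signs mean a
  # crossing between them (possibly sitting exactly on one or two flat
  # grid points); equal signs across a short flat run mean a tangency.
  sgn <- sign(gv)
  sgn[is_flat] <- 0
  nz <- which(sgn != 0)
  if (length(nz) >= 2L) {
    for (k in seq_len(length(nz) - 1L)) {
      i <- nz[k]
      j <- nz[k + 1L]
      if (sgn[i] != sgn[j]) {
        root <- if (j == i + 1L) {
          stats::uniroot(g, c(grid[i], grid[j]), tol = tol)$root
        } else {
          mean(grid[(i + 1L):(j - 1L)])   # crossing pinned on flat points
        }
        if (in_continuum(root)) next
        p_star <- c(p_star, root)
        kind <- c(kind, "interior")
        stability <- c(stability, if (sgn[i] > 0) "stable" else "unstable")
      } else if (j > i + 1L) {
        root <- mean(grid[(i + 1L):(j - 1L)])
        if (in_continuum(root)) next
        p_star <- c(p_star, root)
        kind <- c(kind, "interior")
        stability <- c(stability, "marginal")   # touches zero, no sign change
      }
    }
  }

  g0 <- gv[1L]
  g1 <- gv[length(gv)]
  if (g0 <= flat_tol) {                      # B(0) <= C(0)
    p_star <- c(p_star, 0)
    kind <- c(kind, "boundary")
    stability <- c(stability,
                   if (g0 < -flat_tol) "stable" else "marginal")
  }
  if (g1 >= -flat_tol) {                     # B(1) >= C(1)
    p_star <- c(p_star, 1)
    kind <- c(kind, "boundary")
    stability <- c(stability,
                   if (g1 > flat_tol) "stable" else "marginal")
  }

  ord <- order(p_star)
  eq <- tibble::tibble(p_star = p_star[ord], kind = kind[ord],
                       stability = stability[ord])
  structure(
    list(equilibria = eq,
         feedback_class = classify_feedback(game, grid, gv),
         gap_samples = benefit_cost_curves(game, grid),
         continua = continua),
    class = "equilibrium_set")
}

#' @export
print.equilibrium_set <- function(x, ...) {
  cat("<equilibrium_set>\n")
  cat(sprintf("  strategic feedback: %s%s\n", x$feedback_class,
              if (isTRUE(attr(x$feedback_class, "flat"))) " (flat gap)" else ""))
  if (length(x$continua)) {
    for (iv in x$continua) {
      cat(sprintf("  continuum of equilibria on [%.4g, %.4g]\n",
                  iv[1L], iv[2L]))
    }
  }
  eq <- x$equilibria
  if (nrow(eq) == 0L) {
    cat("  no isolated equilibria\n")
  } else {
    for (i in seq_len(nrow(eq))) {
      cat(sprintf("  p* = %.6g (%s, %s)\n",
                  eq$p_star[i], eq$kind[i], eq$stability[i]))
    }
  }
  invisible(x)
}

#' Classify the strategic feedback of a game
#'
#' Strategic substitutes (negative feedback): the net incentive
#' `B(p) - C(p)` falls as more managers steward, so others' stewardship
#' crowds out one's own. Strategic complements (positive feedback): the
#' net incentive rises with `p`, so stewardship is self-reinforcing.
#' Non-monotone games are `"mixed"`. A numerically constant gap is
#' classified as weakly negative with attribute `flat = TRUE`.
#'
#' @param game A [population_game()].
#' @param p_grid Grid on which monotonicity is assessed (>= 3 points).
#' @param gap_values Optional precomputed `B - C` on `p_grid`.
#' @return `"negative"`, `"positive"`, or `"mixed"` (with attribute
#'   `flat`).
#' @export
classify_feedback <- function(game, p_grid = seq(0, 1, by = 0.01),
                              gap_values = NULL) {
  stopifnot(inherits(game, "population_game"))
  if (length(p_grid) < 3L) abort_validation("p_grid needs at least 3 points")
  gv <- gap_values %||% game_gap_fn(game)(p_grid)
  d <- diff(gv)
  tol <- .REL_TOL * max(1, max(abs(gv)))
  if (all(abs(d) <= tol)) {
    return(structure("negative", flat = TRUE))
  }
  if (all(d <= tol)) return(structure("negative", flat = FALSE))
  if (all(d >= -tol)) return(structure("positive", flat = FALSE))
  structure("mixed", flat = FALSE)
}

#' Best-response adjustment dynamics
#'
#' Myopic population adjustment: the stewarding fraction drifts up where
#' stewardship currently pays (`B(p) > C(p)`) and down where it does not,
#' `p <- clip(p + step * tanh((B(p) - C(p)) / epsilon), 0, 1)`.
#' The smooth sign (`epsilon` small) avoids chattering at the root, and
#' the step is halved each time the drift direction flips, so the
#' iteration settles onto a convergence-stable equilibrium rather than
#' oscillating around it. Only the limit set matters: it coincides with
#' the stable members of [find_nash_equilibria()].
#'
#' @param game A [population_game()].
#' @param p_init Initial stewarding fraction in `[0, 1]`.
#' @param step_rate Initial step size in `(0, 1]`.
#' @param max_steps Iteration cap.
#' @param tol Convergence tolerance on the step.
#' @param epsilon Smoothing width of the sign function.
#' @return List with `trajectory` (numeric vector starting at `p_init`),
#'   `limit` (final point), and `converged`.
#' @export
best_response_dynamics <- function(game, p_init, step_rate = 0.05,
                                   max_steps = 10000L, tol = 1e-8,
                                   epsilon = 1e-3) {
  stopifnot(inherits(game, "population_game"))
  check_number(p_init, "p_init", lower = 0, upper = 1)
  check_number(step_rate, "step_rate", lower = 0, upper = 1,
               strict_lower = TRUE)
  g <- game_gap_fn(game)

  p <- p_init
  traj <- p
  step <- step_rate
  prev_dir <- 0
  converged <- FALSE
  for (i in seq_len(max_steps)) {
    drift <- tanh(g(p) / epsilon)
    delta <- step * drift
    dir <- sign(delta)
    if (dir != 0 && prev_dir != 0 && dir != prev_dir) step <- step / 2
    prev_dir <- if (dir != 0) dir else prev_dir
    p_new <- min(max(p + step * drift, 0), 1)
    traj <- c(traj, p_new)
    if (abs(p_new - p) < tol) {
      p <- p_new
      converged <- TRUE
      break
    }
    p <- p_new
  }
  list(trajectory = traj, limit = p, converged = converged)
}
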