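#' Catalog of worked-example fixtures
#'
#' Named builders for the scenarios and games used throughout the
#' documentation and tests, so every analysis in the package can be
#' exercised without external data:
#'
#' * `bt_binary` — Bt-corn refuge as a binary choice: plant no refuge or
#'   a 20% refuge. Calibrated so the no-refuge effective life span is 8
#'   effective years and the refuge raises it by 30% (beating the 25%
#'   percentage cost of a 20% refuge).
#' * `bt_continuous` — Bt-corn refuge over a continuum of fractions with
#'   linear profit and persistence curves.
#' * `fig3a_substitutes` — population game with negative strategic
#'   feedback (`B(p) = 0.5 - 0.3 p`, `C(p) = 0.2 + 0.2 p`): a unique
#'   interior stable equilibrium where the curves cross at `p = 0.6`.
#' * `fig3b_complements` — positive strategic feedback
#'   (`B(p) = 0.1 + 0.6 p`, `C(p) = 0.3 + 0.2 p`): stable equilibria at
#'   `p = 0` and `p = 1` separated by an unstable crossing at `p = 0.5`.
#' * `hospital_tracing` — contact-tracing game in which an individual
#'   hospital's investment barely affects resistance spread
#'   (`L_p(g) = L_p(g0)`, so `B` is identically 0) while tracing costs
#'   are real: no hospital stewards on its own.
#' * `reversible_demo` — a constant-curve scenario (excess profit 1 per
#'   year, persistence 0.8, discount factor 0.9) bundled with a default
#'   reversal probability `rho = 0.1` for [simulate_reversible()].
#'
#' @param name One of the catalog names; see [fixture_names()].
#' @return The built `management_scenario` or `population_game`.
#'   `reversible_demo` carries the default `rho` as attribute `"rho"`.
#' @examples
#' find_nash_equilibria(build_fixture("fig3a_substitutes"))
#' @export
build_fixture <- function(name) {
  if (!name %in% fixture_names()) {
    abort_validation("unknown fixture '%s'; available: %s",
                     name, paste(fixture_names(), collapse = ", "))
  }
  switch(name,
    bt_binary = {
      delta <- 0.95
      management_scenario(
        pristine_profit = parametric_fn("linear",
                                        list(intercept = 100, slope = -40)),
        evolved_profit = 60,
        # calibrated: L(0) = 8 effective years, L(0.2) = 10.4 (a 30% gain)
        persistence = parametric_fn("table",
          list(x = c(0, 0.2), y = c((1 - 1 / 8) / delta,
                                    (1 - 1 / 10.4) / delta))),
        actions = action_grid(c(0, 0.2)),
        discount_factor = delta)
    },
    bt_continuous = management_scenario(
      pristine_profit = parametric_fn("linear",
                                      list(intercept = 100, slope = -40)),
      evolved_profit = 60,
      persistence = parametric_fn("linear",
                                  list(intercept = 0.8, slope = 0.15)),
      actions = action_interval(0, 1),
      discount_factor = 0.95),
    fig3a_substitutes = population_game(
      excess_steward = 1,
      excess_nosteward = parametric_fn("linear",
                                       list(intercept = 1.2, slope = 0.2)),
      lifespan_steward = parametric_fn("linear",
                                       list(intercept = 7.5, slope = -1.5)),
      lifespan_nosteward = 5,
      description = "negative strategic feedback (strategic substitutes)"),
    fig3b_complements = population_game(
      excess_steward = 1,
      excess_nosteward = parametric_fn("linear",
                                       list(intercept = 1.3, slope = 0.2)),
      lifespan_steward = parametric_fn("linear",
                                       list(intercept = 5.5, slope = 3)),
      lifespan_nosteward = 5,
      description = "positive strategic feedback (strategic complements)"),
    hospital_tracing = population_game(
      excess_steward = 0.9,
      excess_nosteward = 1,
      lifespan_steward = parametric_fn("linear",
                                       list(intercept = 4, slope = 4)),
      lifespan_nosteward = parametric_fn("linear",
                                         list(intercept = 4, slope = 4)),
      description = "individual tracing has negligible effect on spread"),
    reversible_demo = {
      sc <- management_scenario(
        pristine_profit = 100,
        evolved_profit = 99,
        persistence = 0.8,
        actions = action_grid(c(0, 1)),
        discount_factor = 0.9)
      attr(sc, "rho") <- 0.1
      sc
    })
}

#' @rdname build_fixture
#' @export
fixture_names <- function() {
  c("bt_binary", "bt_continuous", "fig3a_substitutes",
    "fig3b_complements", "hospital_tracing", "reversible_demo")
}

#' Write a fixture's config and expected headline numbers to disk
#'
#' Serializes the named fixture to `<name>.yaml` in `dir` and writes a
#' companion `<name>_expected.json` with the headline quantities the
#' fixture is built to exhibit (evaluation or equilibrium structure), for
#' use as regression anchors.
#'
#' @inheritParams build_fixture
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
generate_fixture <- function(name, dir = ".") {
  obj <- build_fixture(name)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cfg_path <- file.path(dir, paste0(name, ".yaml"))
  write_scenario(obj, cfg_path)

  expected <- if (inherits(obj, "management_scenario")) {
    grid <- probe_actions(obj$actions, 11L)
    ev <- evaluate_action(obj, grid[which.max(
      vapply(grid, function(g) {
        (obj$pristine_profit(g) - obj$evolved_profit) /
          (1 - obj$delta * obj$persistence(g))
      }, numeric(1)))])
    list(kind = "management_scenario", gamma = ev$gamma, E = ev$E,
         L = ev$L, V = ev$V, beneficial = ev$beneficial)
  } else {
    eq <- find_nash_equilibria(obj)
    list(kind = "population_game",
         feedback = as.character(eq$feedback_class),
         equilibria = eq$equilibria)
  }
  exp_path <- file.path(dir, paste0(name, "_expected.json"))
  jsonlite::write_json(expected, exp_path, auto_unbox = TRUE, digits = NA)
  invisible(c(cfg_path, exp_path))
}

# ---- configuration files ----------------------------------------------

scenario_keys <- c("type", "discount", "pristine_profit", "evolved_profit",
                   "persistence", "actions", "gamma0")
game_keys <- c("type", "excess_steward", "excess_nosteward",
               "lifespan_steward", "lifespan_nosteward", "description")

#' Read a scenario or game from a YAML/JSON config file
#'
#' The config dialect mirrors the constructors. A management scenario:
#' ```yaml
#' discount: {rate: 0.04}            # or {factor: 0.9}
#' pristine_profit: {family: linear, params: {intercept: 100, slope: -40}}
#' evolved_profit: 60
#' persistence: {family: linear, params: {intercept: 0.8, slope: 0.15}}
#' actions: {type: interval, bounds: [0, 1]}   # or {type: grid, values: [...]}
#' ```
#' A population game is marked `type: population_game` and carries the
#' four curve entries `excess_steward`, `excess_nosteward`,
#' `lifespan_steward`, `lifespan_nosteward`. Unknown keys are rejected by
#' name; all type invariants are validated on load.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `management_scenario` or `population_game`.
#' @seealso [write_scenario()] for the inverse.
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) abort_validation("config file not found: %s", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  config_to_object(cfg, path)
}

config_to_object <- function(cfg, path = "<config>") {
  if (!is.list(cfg)) abort_validation("%s does not parse to a mapping", path)
  type <- cfg$type %||%
    if (!is.null(cfg$pristine_profit)) "management_scenario"
    else if (!is.null(cfg$excess_steward)) "population_game"
    else abort_validation("%s: cannot infer config type", path)

  if (type == "management_scenario") {
    extra <- setdiff(names(cfg), scenario_keys)
    if (length(extra)) {
      abort_validation("%s: unknown key(s): %s", path,
                       paste(extra, collapse = ", "))
    }
    for (key in c("discount", "pristine_profit", "evolved_profit",
                  "persistence", "actions")) {
      if (is.null(cfg[[key]])) {
        abort_validation("%s: missing required key `%s`", path, key)
      }
    }
    d <- cfg$discount
    extra <- setdiff(names(d), c("rate", "factor"))
    if (length(extra)) {
      abort_validation("%s: unknown discount key(s): %s", path,
                       paste(extra, collapse = ", "))
    }
    management_scenario(
      pristine_profit = as_curve(cfg$pristine_profit, "pristine_profit"),
      evolved_profit = cfg$evolved_profit,
      persistence = as_curve(cfg$persistence, "persistence"),
      actions = as_actions(cfg$actions),
      rate = d$rate, discount_factor = d$factor,
      gamma0 = cfg$gamma0)
  } else if (type == "population_game") {
    extra <- setdiff(names(cfg), game_keys)
    if (length(extra)) {
      abort_validation("%s: unknown key(s): %s", path,
                       paste(extra, collapse = ", "))
    }
    for (key in c("excess_steward", "excess_nosteward",
                  "lifespan_steward", "lifespan_nosteward")) {
      if (is.null(cfg[[key]])) {
        abort_validation("%s: missing required key `%s`", path, key)
      }
    }
    population_game(
      excess_steward = as_curve(cfg$excess_steward, "excess_steward"),
      excess_nosteward = as_curve(cfg$excess_nosteward, "excess_nosteward"),
      lifespan_steward = as_curve(cfg$lifespan_steward, "lifespan_steward"),
      lifespan_nosteward = as_curve(cfg$lifespan_nosteward,
                                    "lifespan_nosteward"),
      description = cfg$description)
  } else {
    abort_validation("%s: unknown config type '%s'", path, type)
  }
}

#' Write a scenario or game to a YAML/JSON config file
#'
#' Only curves built from named parametric families can be serialized;
#' custom R functions raise an error.
#'
#' @param x A `management_scenario` or `population_game`.
#' @param path Output path ending in `.yaml`, `.yml`, or `.json`.
#' @return Invisibly, `path`.
#' @export
write_scenario <- function(x, path) {
  cfg <- object_to_config(x)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(cfg, path, precision = 15)  # round-trip at full precision
  }
  invisible(path)
}

object_to_config <- function(x) {
  if (inherits(x, "management_scenario")) {
    acts <- if (x$actions$type == "grid") {
      list(type = "grid", values = x$actions$values)
    } else {
      list(type = "interval", bounds = x$actions$bounds)
    }
    list(type = "management_scenario",
         discount = list(factor = x$delta),
         pristine_profit = curve_spec(x$pristine_profit),
         evolved_profit = x$evolved_profit,
         persistence = curve_spec(x$persistence),
         actions = acts,
         gamma0 = x$gamma0)
  } else if (inherits(x, "population_game")) {
    out <- list(type = "population_game",
                excess_steward = curve_spec(x$excess_steward),
                excess_nosteward = curve_spec(x$excess_nosteward),
                lifespan_steward = curve_spec(x$lifespan_steward),
                lifespan_nosteward = curve_spec(x$lifespan_nosteward))
    if (!is.null(x$description)) out$description <- x$description
    out
  } else {
    abort_validation("cannot serialize object of class %s",
                     paste(class(x), collapse = "/"))
  }
}
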