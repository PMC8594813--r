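test_that("every fixture builds, validates, and round-trips through YAML and JSON", {
  for (name in fixture_names()) {
    obj <- build_fixture(name)
    expect_true(inherits(obj, "management_scenario") ||
                  inherits(obj, "population_game"), info = name)

    for (ext in c(".yaml", ".json")) {
      path <- withr::local_tempfile(fileext = ext)
      write_scenario(obj, path)
      back <- load_scenario(path)
      if (inherits(obj, "management_scenario")) {
        g <- probe_grid <- seq_along(1:5) / 5
        expect_equal(back$delta, obj$delta, info = name)
        expect_equal(back$gamma0, obj$gamma0, info = name)
        gs <- if (obj$actions$type == "grid") obj$actions$values
              else probe_grid
        for (gamma in gs) {
          expect_equal(evaluate_action(back, gamma)$V,
                       evaluate_action(obj, gamma)$V, info = name)
        }
      } else {
        p <- c(0, 0.37, 1)
        expect_equal(benefit_cost_curves(back, p),
                     benefit_cost_curves(obj, p), info = name)
      }
    }
  }
})

test_that("configs with a 4% rate load with delta = 1/1.04", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "discount: {rate: 0.04}",
    "pristine_profit: {family: linear, params: {intercept: 100, slope: -40}}",
    "evolved_profit: 60",
    "persistence: {family: constant, params: {value: 0.9}}",
    "actions: {type: interval, bounds: [0, 1]}"), path)
  sc <- load_scenario(path)
  expect_equal(sc$delta, 0.9615385, tolerance = 1e-7)
})

test_that("the config schema rejects invariant-violating inputs by name", {
  write_cfg <- function(lines) {
    path <- withr::local_tempfile(fileext = ".yaml", .local_envir = parent.frame())
    writeLines(lines, path)
    path
  }
  base <- c(
    "pristine_profit: {family: linear, params: {intercept: 100, slope: -40}}",
    "evolved_profit: 60",
    "persistence: {family: constant, params: {value: 0.9}}",
    "actions: {type: interval, bounds: [0, 1]}")

  expect_error(load_scenario(write_cfg(c("discount: {rate: 0.04, factor: 0.9}", base))),
               "disagree")
  expect_error(load_scenario(write_cfg(c("discount: {rate: 0.04}", base,
                                         "surprise_key: 1"))),
               "unknown key.*surprise_key")
  expect_error(load_scenario(write_cfg(base)), "missing required key `discount`")
  expect_error(load_scenario(write_cfg(c(
    "discount: {rate: 0.04}",
    "pristine_profit: {family: linear, params: {intercept: 100, slope: -40}}",
    "evolved_profit: 200",
    "persistence: {family: constant, params: {value: 0.9}}",
    "actions: {type: interval, bounds: [0, 1]}"))),
    "must exceed evolved profit")
  expect_error(load_scenario(write_cfg(c(
    "discount: {rate: 0.04}",
    "pristine_profit: {family: linear, params: {intercept: 100, slope: -40}}",
    "evolved_profit: 60",
    "persistence: {family: constant, params: {value: 1.7}}",
    "actions: {type: interval, bounds: [0, 1]}"))),
    "\\[0, 1\\]")
  expect_error(load_scenario("/nonexistent/file.yaml"), "not found")
})

test_that("fixture generation writes configs plus expected-output anchors", {
  dir <- withr::local_tempdir()
  paths <- generate_fixture("fig3a_substitutes", dir = dir)
  expect_true(all(file.exists(paths)))
  expected <- jsonlite::read_json(file.path(dir, "fig3a_substitutes_expected.json"),
                                  simplifyVector = TRUE)
  expect_equal(expected$kind, "population_game")
  expect_equal(expected$feedback, "negative")
  expect_error(build_fixture("nope"), "unknown fixture.*bt_binary")
})

test_that("unknown parametric families and custom functions fail serialization cleanly", {
  expect_error(parametric_fn("spline", list()), "'arg' should be one of")
  expect_error(parametric_fn("linear", list(intercept = 1)), "requires parameter")
  g <- population_game(excess_steward = function(p) 1 + 0 * p,
                       excess_nosteward = 1.2,
                       lifespan_steward = 7, lifespan_nosteward = 5)
  expect_error(write_scenario(g, withr::local_tempfile(fileext = ".yaml")),
               "cannot be serialized")
})

# ---- command-line interface -------------------------------------------

cli_json <- function(args) {
  out <- capture.output(status <- run_cli(args))
  list(status = status, json = jsonlite::fromJSON(paste(out, collapse = "")))
}

test_that("the CLI computes refuge numbers and lists fixtures", {
  res <- cli_json(c("refuge", "cost", "--gamma", "0.2"))
  expect_equal(res$status, 0L)
  expect_equal(res$json$cost_pct, 0.25)

  res2 <- cli_json(c("refuge", "lifespan-gain", "--L0", "8", "--gamma", "0.2"))
  expect_equal(res2$json$required_gain, 2)

  res3 <- cli_json(c("refuge", "calendar", "--N", "15", "--gamma", "0.26",
                     "--rate", "0.04"))
  expect_equal(res3$json$M_years, 24)

  res4 <- cli_json(c("fixtures", "--list"))
  expect_setequal(res4$json$fixtures, fixture_names())

  res5 <- cli_json(c("critical-discount", "--kappa-gamma", "0.95",
                     "--kappa-gamma0", "0.8", "--cost-ratio", "0.25"))
  expect_equal(res5$json$delta_star, 0.25 / 0.3875, tolerance = 1e-9)
})

test_that("the CLI runs scenario and game analyses from config files", {
  dir <- withr::local_tempdir()
  generate_fixture("bt_binary", dir = dir)
  generate_fixture("fig3a_substitutes", dir = dir)
  sc_cfg <- file.path(dir, "bt_binary.yaml")
  game_cfg <- file.path(dir, "fig3a_substitutes.yaml")

  ev <- cli_json(c("evaluate", "--config", sc_cfg, "--gamma", "0.2"))
  expect_true(ev$json$beneficial)
  expect_equal(ev$json$B, 0.3, tolerance = 1e-9)

  opt <- cli_json(c("optimize", "--config", sc_cfg))
  expect_equal(opt$json$optimal_action, 0.2)

  sim1 <- cli_json(c("simulate", "--config", sc_cfg, "--gamma", "0.2",
                     "--reps", "1000", "--seed", "7"))
  sim2 <- cli_json(c("simulate", "--config", sc_cfg, "--gamma", "0.2",
                     "--reps", "1000", "--seed", "7"))
  expect_identical(sim1$json, sim2$json)
  expect_lt(abs(sim1$json$mean_pv - sim1$json$analytic_pv),
            5 * sim1$json$std_error)

  nash <- cli_json(c("nash", "--game", game_cfg))
  expect_equal(nash$json$equilibria$p_star, 0.6, tolerance = 1e-9)

  dyn <- cli_json(c("dynamics", "--game", game_cfg, "--p0", "0.1"))
  expect_equal(dyn$json$limit, 0.6, tolerance = 1e-6)

  pol <- cli_json(c("policy", "switching-subsidy", "--game", game_cfg))
  expect_equal(pol$json$S_star, 0.2 / 1.2, tolerance = 1e-9)
})

test_that("the CLI distinguishes usage errors from validation errors", {
  expect_equal(suppressMessages(run_cli(character(0))), 2L)
  expect_equal(suppressMessages(run_cli(c("frobnicate"))), 2L)
  expect_equal(suppressMessages(run_cli(c("refuge", "cost"))), 2L)
  expect_equal(suppressMessages(run_cli(c("refuge", "cost", "--gamma", "1.2"))), 1L)
  expect_equal(suppressMessages(
    run_cli(c("evaluate", "--config", "/no/such.yaml", "--gamma", "0.2"))), 1L)
})
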