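test_that("effective life span matches the geometric closed form and its bounds", {
  expect_equal(effective_lifespan(0.9, 1), 10)
  expect_equal(effective_lifespan(0, 0.99), 1)
  # delta * kappa = 0.875 gives an 8-effective-year stream
  expect_equal(effective_lifespan(0.95, 0.875 / 0.95), 8)

  withr::with_seed(11, {
    for (i in 1:50) {
      delta <- runif(1, 0, 0.99)
      kappa <- runif(1)
      L <- effective_lifespan(delta, kappa)
      expect_gte(L, 1)
      expect_lte(L, 1 / (1 - delta) + 1e-12)
      # nondecreasing in each argument
      expect_gte(effective_lifespan(min(delta * 1.01, 0.999), kappa), L)
      expect_gte(effective_lifespan(delta, min(kappa * 1.01, 1)), L)
    }
  })
})

test_that("effective life span rejects divergent and out-of-range inputs", {
  expect_error(effective_lifespan(1, 1), "non-finite lifespan")
  expect_error(effective_lifespan(-0.1, 0.5), "valid range")
  expect_error(effective_lifespan(0.5, 1.2), "valid range")
})

test_that("excess profit is pristine profit over the evolved baseline", {
  sc <- management_scenario(
    pristine_profit = parametric_fn("linear", list(intercept = 100, slope = -40)),
    evolved_profit = 60,
    persistence = 0.9,
    actions = action_interval(0, 1),
    discount_factor = 0.9)
  expect_equal(excess_profit(sc, 0), 40)
  expect_equal(excess_profit(sc, 0.2), 32)   # (1-0.2)*100 + 0.2*60 - 60
  expect_equal(excess_profit(sc, 1), 0)
  expect_error(excess_profit(sc, 1.5), "not in the scenario's action set")
})

test_that("stream value equals the truncated geometric series to its tail bound", {
  expect_equal(stream_value(0, 5), 0)
  expect_equal(stream_value(60, 10), 600)

  dk <- 0.9
  E <- 1
  exact <- stream_value(E, 1 / (1 - dk))
  for (T in c(5, 20, 100, 300)) {
    partial <- sum(dk^(0:T) * E)
    tail_bound <- dk^(T + 1) / (1 - dk) * E
    expect_lte(abs(exact - partial), tail_bound + 1e-12)
  }
  expect_equal(sum(0.9^(0:300)), 10, tolerance = 1e-12)
})

test_that("the scenario constructor enforces the model's assumptions", {
  lin <- function(a, b) parametric_fn("linear", list(intercept = a, slope = b))
  expect_error(
    management_scenario(lin(100, -40), 60, 0.9, action_interval(0, 1),
                        rate = 0.04, discount_factor = 0.9),
    "disagree")
  expect_error(
    management_scenario(lin(100, -40), 120, 0.9, action_interval(0, 1),
                        discount_factor = 0.9),
    "must exceed evolved profit")
  expect_error(
    management_scenario(lin(100, -40), 60, lin(0.8, 0.5),
                        action_interval(0, 1), discount_factor = 0.9),
    "\\[0, 1\\]")

  # gamma0 is the excess-profit maximizer; ties break toward smaller gamma
  sc <- management_scenario(lin(100, -40), 60, 0.9, action_interval(0, 1),
                            discount_factor = 0.9)
  expect_equal(sc$gamma0, 0)
  sc2 <- management_scenario(lin(100, 40), 60, 0.9, action_interval(0, 1),
                             discount_factor = 0.9)
  expect_equal(sc2$gamma0, 1)
  sc3 <- management_scenario(100, 60, 0.9, action_grid(c(0, 0.5, 1)),
                             discount_factor = 0.9)
  expect_equal(sc3$gamma0, 0)
  expect_warning(
    management_scenario(lin(100, -40), 60, 0.9, action_interval(0, 1),
                        discount_factor = 0.9, gamma0 = 0.5),
    "does not maximize")
})

test_that("a rate of 4% implies a discount factor of 1/1.04", {
  sc <- management_scenario(100, 60, 0.9, action_grid(0), rate = 0.04)
  expect_equal(sc$delta, 1 / 1.04)
  expect_equal(sc$delta, 0.9615385, tolerance = 1e-6)
})

test_that("evaluating gamma0 against itself is a tie, never beneficial", {
  sc <- build_fixture("bt_binary")
  ev <- evaluate_action(sc, sc$gamma0)
  expect_equal(ev$benefit_pct, 0)
  expect_equal(ev$cost_pct, 0)
  expect_false(ev$beneficial)
  expect_true(ev$tie)
})

test_that("the knife-edge refuge (25% gain vs 25% cost) is not beneficial", {
  delta <- 0.95
  sc <- management_scenario(
    pristine_profit = parametric_fn("table", list(x = c(0, 0.2), y = c(100, 92))),
    evolved_profit = 60,
    persistence = parametric_fn("table",
      list(x = c(0, 0.2), y = c(0.875 / delta, 0.9 / delta))),
    actions = action_grid(c(0, 0.2)),
    discount_factor = delta)
  ev <- evaluate_action(sc, 0.2)
  expect_equal(ev$L / ev$L0, 1.25, tolerance = 1e-12)   # 10 vs 8 effective years
  expect_equal(ev$cost_pct, 0.25, tolerance = 1e-12)
  expect_true(ev$tie)
  expect_false(ev$beneficial)
})

test_that("the inequality decision agrees with the direct present-value comparison", {
  withr::with_seed(42, {
    for (i in 1:200) {
      sc <- random_scenario()
      gamma <- runif(1)
      ev <- evaluate_action(sc, gamma)
      expect_true(ev$percentage_form)
      expect_identical(ev$beneficial, !ev$tie && ev$V > ev$V0)
    }
  })
})

test_that("non-positive excess profit falls back to the direct value comparison", {
  sc <- management_scenario(
    pristine_profit = parametric_fn("linear", list(intercept = 100, slope = -80)),
    evolved_profit = 60,
    persistence = 0.9,
    actions = action_interval(0, 1),
    discount_factor = 0.9)
  ev <- evaluate_action(sc, 0.8)    # Pi = 36 < 60, E < 0
  expect_false(ev$percentage_form)
  expect_true(is.na(ev$benefit_pct))
  expect_false(ev$beneficial)       # negative stream can never beat positive
})

test_that("the expanded inequality is algebraically equivalent to the ratio form", {
  # complete discounting or ineffective management kill the incentive
  z <- evaluate_action_expanded(0, 0.95, 0.8, 90, 100, 60)
  expect_equal(z$lhs, 0)
  expect_false(z$beneficial)
  z2 <- evaluate_action_expanded(0.9, 0.8, 0.8, 90, 100, 60)
  expect_equal(z2$lhs, 0)
  expect_false(z2$beneficial)

  withr::with_seed(7, {
    for (i in 1:200) {
      sc <- random_scenario()
      gamma <- runif(1)
      ev <- evaluate_action(sc, gamma)
      ex <- evaluate_action_expanded(
        sc$delta, sc$persistence(gamma), sc$persistence(sc$gamma0),
        sc$pristine_profit(gamma), sc$pristine_profit(sc$gamma0),
        sc$evolved_profit)
      expect_identical(ev$beneficial, ex$beneficial)
    }
  })
})

test_that("a poorer evolved state never turns a beneficial action unprofitable", {
  withr::with_seed(13, {
    for (i in 1:100) {
      sc <- random_scenario()
      gamma <- runif(1)
      ev <- evaluate_action(sc, gamma)
      lower <- management_scenario(
        pristine_profit = sc$pristine_profit,
        evolved_profit = sc$evolved_profit - runif(1, 0, 20),
        persistence = sc$persistence,
        actions = sc$actions,
        discount_factor = sc$delta)
      ev2 <- evaluate_action(lower, gamma)
      if (ev$beneficial) expect_true(ev2$beneficial)
    }
  })
})
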