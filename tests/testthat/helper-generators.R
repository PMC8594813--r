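# Random model generators used across property-style tests.

# A random linear-curve scenario on the continuous action set [0, 1].
# Built so that Pi(gamma) > evolved_profit everywhere (excess profit
# stays positive) and kappa is nondecreasing in gamma within [0, 1].
random_scenario <- function() {
  delta <- runif(1, 0.05, 0.98)
  pibar <- runif(1, 0, 50)
  a <- pibar + runif(1, 5, 100)
  b <- runif(1, -0.9 * (a - pibar), 0)   # stewardship costs profit: gamma0 = 0
  k0 <- runif(1, 0.3, 0.95)
  k1 <- runif(1, 0, 1 - k0)
  management_scenario(
    pristine_profit = parametric_fn("linear", list(intercept = a, slope = b)),
    evolved_profit = pibar,
    persistence = parametric_fn("linear", list(intercept = k0, slope = k1)),
    actions = action_interval(0, 1),
    discount_factor = delta)
}

# A random binary-choice population game with linear benefit and cost
# curves, hence a monotone incentive gap (pure negative or positive
# strategic feedback, depending on the drawn slopes).
random_monotone_game <- function() {
  b0 <- runif(1, -0.1, 0.6)
  b1 <- runif(1, -0.3, 0.5)
  c0 <- runif(1, 0, 0.5)
  c1 <- runif(1, -0.4, 0.4)
  Eg <- runif(1, 0.5, 2)
  L0 <- runif(1, 3, 10)
  population_game(
    excess_steward = Eg,
    excess_nosteward = parametric_fn("linear",
      list(intercept = Eg * (1 + c0), slope = Eg * c1)),
    lifespan_steward = parametric_fn("linear",
      list(intercept = L0 * (1 + b0), slope = L0 * b1)),
    lifespan_nosteward = L0)
}

# Negative strategic feedback with a positive stewardship externality:
# B(p) = 0.5 + 0.1 p, C(p) = 0.2 + 0.6 p, so the gap falls in p (unique
# stable crossing at p = 0.6) while E_p(g) L_p(g) = 7.5 + 0.5 p rises.
cartel_demo_game <- function() {
  population_game(
    excess_steward = 1,
    excess_nosteward = parametric_fn("linear",
                                     list(intercept = 1.2, slope = 0.6)),
    lifespan_steward = parametric_fn("linear",
                                     list(intercept = 7.5, slope = 0.5)),
    lifespan_nosteward = 5,
    description = "negative feedback, positive externality")
}

stable_points <- function(eqset) {
  eqset$equilibria$p_star[eqset$equilibria$stability == "stable"]
}
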