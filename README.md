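# evomanage

Economic decision analysis for managing resistance evolution.

Farmers who plant refuges next to Bt crops, physicians who add partner
drugs to a new antimicrobial, hospitals that fund contact tracing — all
give up profit today to slow the evolution that would destroy a
profitable resource tomorrow. `evomanage` answers the manager's
question: **when does that trade pay for itself?**

## The model in one inequality

Adverse evolution is treated as an irreversible regime shift. In the
pristine state an action γ earns Π(γ) per year; after the shift profit
drops to the constant Π̄, leaving the *excess profit*
E(γ) = Π(γ) − Π̄ at stake. With annual discount factor δ = 1/(1 + r)
and annual persistence probability κ(γ) that evolution does not occur,
the excess stream is worth

    E(γ) · L(γ),    L(γ) = 1 / (1 − δ·κ(γ)),

where L is the *effective life span* — the number of effective years the
stream is worth. Stewardship action γ beats the no-stewardship choice
γ₀ exactly when the **evolution management inequality** holds:

    L(γ) − L(γ₀)        E(γ₀) − E(γ)
    ────────────   >    ────────────
       L(γ₀)                E(γ)

i.e. when the percentage gain in effective life span exceeds the
percentage of annual excess profit forgone. On top of this the package
builds single-manager optimization (`optimal_action()`,
`critical_discount_factor()`), the Bt-refuge worked example
(`refuge_cost_percentage()`, `min_calendar_lifespan()`), a Monte Carlo
regime-shift simulator with a reversible two-state variant
(`simulate_pristine_stream()`, `simulate_reversible()`), a population
game for interacting managers with Nash equilibria and convergence
stability (`find_nash_equilibria()`, `best_response_dynamics()`), and
policy analysis of subsidies and cartels (`minimum_switching_subsidy()`,
`temporary_subsidy_outcome()`, `collective_optimum()`).

## Worked example: is a 20% Bt refuge worth it?

A refuge of fraction γ costs γ/(1−γ) of annual excess profit whenever
the farmer would keep planting non-Bt corn after resistance spreads —
per-acre prices cancel. So a 20% refuge costs 25%, and it pays only if
it raises the effective life span by more than 25%. The `bt_binary`
fixture is calibrated with an 8-effective-year baseline and a refuge
that buys a 30% gain:

```r
library(evomanage)
sc <- build_fixture("bt_binary")
evaluate_action(sc, 0.2)
#> <stewardship_evaluation>
#>   action gamma = 0.2 (vs gamma0 = 0)
#>   excess profit E = 32/yr, effective life span L = 10.4
#>   present value V = 332.8 (vs V0 = 320)
#>   benefit B = 30%, cost C = 25%
#>   beneficial: TRUE
```

The refuge sacrifices 8/yr of excess profit (32 vs 40) but stretches the
effective life span from 8 to 10.4 effective years; a 30% life-span gain
beats the 25% cost, so the stream's present value rises from 320 to
332.8 and the refuge is beneficial.

In calendar terms, a 26% refuge on a crop that would last 15 years must
stretch efficacy to about 23.4 years at a 4% interest rate:

```r
min_calendar_lifespan(N = 15, gamma = 0.26, r = 0.04)
#> smallest calendar life span: 23.43 years (next whole year: 24)
```

When managers interact, the same inequality becomes a game. With
positive strategic feedback (others' stewardship raises your own
incentive) there are two stable equilibria — nobody stewards or
everybody does — and a large one-year subsidy can flip the population
permanently from one to the other:

```r
find_nash_equilibria(build_fixture("fig3b_complements"))
#> <equilibrium_set>
#>   strategic feedback: positive
#>   p* = 0 (boundary, stable)
#>   p* = 0.5 (interior, unstable)
#>   p* = 1 (boundary, stable)
```

## Command line

A thin CLI wraps the same functions (`inst/cli/evomanage` after
install):

```sh
evomanage refuge cost --gamma 0.2                 # {"cost_pct":0.25}
evomanage nash --game fig3a_substitutes.yaml
evomanage simulate --config scenario.yaml --gamma 0.2 --reps 100000 --seed 42
```

Scenario and game configs are YAML/JSON; see `?load_scenario` for the
schema and `?run_cli` for all subcommands.

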