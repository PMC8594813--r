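---
title: "The economics of evolution management: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The economics of evolution management: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evomanage)
```

## The regime-shift model

Resistance evolution — Bt-resistant corn borers, antibiotic-resistant
pathogens — is modelled here as an irreversible jump between two regimes.
While the system is *pristine*, a manager who takes action $\gamma$ (the
refuge fraction, whether to add a partner drug, how much to invest in
contact tracing) earns $\Pi(\gamma)$ per year. Once adverse evolution has
occurred the system is *evolved*: profit drops to the constant
$\bar\Pi$, stewardship stops, and nothing brings the excess back. The
model's assumption $\max_\gamma \Pi(\gamma) > \bar\Pi$ simply says the
shift is economically adverse; the constructor enforces it.

Two kinds of discounting apply to the excess profit
$E(\gamma) = \Pi(\gamma) - \bar\Pi$. Money earned next year is worth
$\delta = 1/(1+r)$ of money today (economic discounting, $r$ the annual
interest rate), and next year's excess exists at all only with the annual
persistence probability $\kappa(\gamma)$ that evolution has not yet
happened (evolutionary discounting). Compounding the two, the stream is
worth

$$E(\gamma) + \delta\kappa(\gamma)\,E(\gamma) +
  (\delta\kappa(\gamma))^2 E(\gamma) + \cdots = E(\gamma)\,L(\gamma),
  \qquad L(\gamma) = \frac{1}{1-\delta\kappa(\gamma)},$$

where $L$, the *effective life span*, is the multiplier that turns one
year's excess profit into the whole stream's present value. $L$ is
always between 1 (complete discounting or certain evolution) and
$1/(1-\delta)$ (no evolution ever).

Comparing a stewardship action $\gamma$ against the no-stewardship
choice $\gamma_0$ (the maximizer of $E$, which the constructor recomputes
rather than trusts) gives the decision rule at the heart of the package,
in two algebraically equivalent dimensionless forms:

$$\underbrace{\frac{L(\gamma)-L(\gamma_0)}{L(\gamma_0)}}_{B,\ \text{% benefit}}
  \;>\;
  \underbrace{\frac{E(\gamma_0)-E(\gamma)}{E(\gamma)}}_{C,\ \text{% cost}}
  \qquad\Longleftrightarrow\qquad
  \frac{\delta\,(\kappa(\gamma)-\kappa(\gamma_0))}{1-\delta\kappa(\gamma)}
  \;>\;
  \frac{\Pi(\gamma_0)-\Pi(\gamma)}{\Pi(\gamma)-\bar\Pi}.$$

Stewardship pays exactly when the percentage gain in effective life span
beats the percentage of annual excess profit forgone. `evaluate_action()`
reports $B$, $C$, and the decision; `evaluate_action_expanded()` reports
the second form; both agree with the direct comparison
$E(\gamma)L(\gamma) > E(\gamma_0)L(\gamma_0)$, and the test suite checks
the three-way agreement on hundreds of random scenarios.

```{r}
sc <- build_fixture("bt_binary")
evaluate_action(sc, 0.2)
```

## Parameters, units, defaults

* **`rate` / `discount_factor`** — annual interest rate $r \ge 0$, or
  equivalently $\delta = 1/(1+r) \in [0,1)$. Supplying both is accepted
  only when they agree; a mismatch is an error rather than a silent
  preference. The Bt calendar-year conversion defaults to $r = 0.04$, a
  conventional long-run real rate for farm investment appraisal.
* **`pristine_profit`, `evolved_profit`** — currency per year, in
  whatever currency unit the user likes; every decision quantity in the
  package is a ratio, so units cancel.
* **`persistence`** — $\kappa(\gamma) \in [0,1]$, the annual probability
  that adverse evolution does *not* occur. $\kappa = 1$ means evolution
  never happens (a valid sentinel in the simulator); $\delta\kappa = 1$
  would make the stream value diverge and is rejected explicitly.
* **Curves** are supplied as named parametric families (`constant`,
  `linear`, `logistic`, `table` with linear interpolation) so that
  scenarios round-trip through YAML/JSON exactly; arbitrary R functions
  are accepted programmatically but refuse to serialize.

### Strictness and ties

"Beneficial" uses the strict inequality $B > C$: an exact tie means the
manager has no reason to move, and `evaluate_action()` reports
`beneficial = FALSE` with `tie = TRUE`. Ties and argmaxes are detected at
relative tolerance `1e-9`; all model quantities are $O(1)$–$O(10^3)$, so
this band is far below economic meaning. Argmax ties break toward
smaller $\gamma$ (less stewardship), mirroring the strict-inequality
convention.

When $E(\gamma) \le 0$ the percentage cost divides by a non-positive
number, so the percentage form is undefined. The evaluation then falls
back to the direct present-value comparison and flags
`percentage_form = FALSE`. This is a package design choice for a corner
the inequality's derivation implicitly excludes, not a claim about the
model's intent; such actions are never beneficial anyway.

## The Bt refuge worked example

For a farmer who would keep planting (non-Bt) corn after resistance
spreads, all per-acre costs and revenues cancel from the cost side and a
refuge of fraction $\gamma$ costs exactly $\gamma/(1-\gamma)$ of annual
excess profit (`refuge_cost_percentage()`): a 20% refuge costs 25%, and
with a baseline effective life span of 8 effective years it must buy at
least $8 \times 0.25 = 2$ extra effective years
(`required_lifespan_gain()`). `alternative_landuse_cost()` drops the
keep-farming assumption: a post-resistance outside option worth more
than non-Bt corn raises the cost percentage monotonically and can make
any refuge uneconomical.

`min_calendar_lifespan()` restates the decision in calendar years for
comparison with multi-year planning models: efficacy is approximated as
lasting a deterministic $T$ years ($\kappa = 1$, then a certain jump),
so a $T$-year stream has finite-horizon effective life span
$L_{\mathrm{fin}}(T) = (1-\delta^T)/(1-\delta)$, and the smallest $M$
with $L_{\mathrm{fin}}(M)/L_{\mathrm{fin}}(N) \ge 1/(1-\gamma)$ is the
break-even calendar life span. At $N = 15$, $\gamma = 0.26$ and the 4%
default rate this gives $M \approx 23.4$ years; because the appropriate
rate is a user judgement, the acceptance tests also record the 3%–5%
band (about 22.4 to 24.8 years), within which the threshold moves
smoothly and monotonically with $r$. Both the real-valued threshold and
its integer ceiling are reported, since "at least $M$ years" can be read
either way. No finite $M$ works when $\delta^N \le \gamma$; that is a
reported outcome, not an exception.

## The Monte Carlo simulator

`simulate_pristine_stream()` validates the closed form $E \cdot L$ by
brute force: shift times are geometric
($\Pr(\text{shift in year } t) = \kappa^{t-1}(1-\kappa)$), profit
accrues at the start of each year and evolution is checked at year end,
so the first year's excess is always earned — matching the leading
undiscounted $E$ term of the stream sum. Replicates are truncated at a
horizon chosen so the neglected tail,
$(\delta\kappa)^T/(1-\delta\kappa)$, is below $10^{-10}$ relative;
a user-supplied smaller horizon warns with the computed bias bound. A
single seeded generator drives each call, so fixed seeds give
bit-identical results.

`simulate_reversible()` relaxes irreversibility with a generic two-state
Markov chain — pristine $\to$ evolved with probability $1-\kappa(\gamma)$
per year, evolved $\to$ pristine with probability $\rho$ — accruing
excess profit only in pristine years (the evolved state pays the
baseline $\bar\Pi$, excess 0). Its exact expectation solves the linear
system $V_p = E + \delta(\kappa V_p + (1-\kappa)V_e)$,
$V_e = \delta(\rho V_p + (1-\rho)V_e)$, which
`reversible_stream_value()` evaluates and the tests use as the oracle;
$\rho = 0$ recovers $E \cdot L$. Whether and how the reversal rate
should itself depend on $\gamma$ is left to the user: $\rho$ is a plain
argument, not a curve.

## Games between managers

When both $E$ and $L$ depend on the fraction $p$ of managers who
steward, the same inequality becomes $B(p) > C(p)$ and the managers play
a population game. The package treats $p$ as a continuum
(infinite-population approximation). Equilibria are found by a
sign-change scan of $g(p) = B(p) - C(p)$ at resolution $10^{-3}$
followed by bisection to $10^{-10}$; crossings that land exactly on grid
points are handled by bracketing between the nearest non-zero samples. A
crossing from positive to negative attracts best-response adjustment and
is convergence stable; $p = 0$ is an equilibrium iff $B(0) \le C(0)$
(stable when strict) and $p = 1$ iff $B(1) \ge C(1)$. Tangencies — the
gap touches zero without changing sign — are labelled *marginal* and
excluded from the stable set, and a gap that is numerically zero over a
stretch of the grid is reported as a continuum rather than collapsed to
an arbitrary point, since nothing in the model selects one.

`best_response_dynamics()` implements the adjustment process whose rest
points define convergence stability:
$p \leftarrow \mathrm{clip}(p + s\,\tanh(g(p)/\varepsilon),\,0,\,1)$
with $\varepsilon = 10^{-3}$, halving the step whenever the drift
reverses direction. The smooth sign and the damping are numerical
devices — only the limit set matters, and the tests verify it coincides
with the stable equilibria across random monotone games.

Two shipped fixtures illustrate the two qualitative regimes with linear
curves. `fig3a_substitutes` ($B = 0.5 - 0.3p$, $C = 0.2 + 0.2p$) has
negative strategic feedback and a unique interior stable equilibrium at
$p^* = 0.6$, where stewards and non-stewards earn identical present
values ($B = C$ forces $E_p(\gamma)L_p(\gamma) =
E_p(\gamma_0)L_p(\gamma_0)$). `fig3b_complements`
($B = 0.1 + 0.6p$, $C = 0.3 + 0.2p$) has positive feedback, stable
equilibria at $p = 0$ and $p = 1$, and an unstable separatrix at
$p = 0.5$. These fixtures are qualitative: their equilibrium structure,
not their particular slopes, is the tested claim. `hospital_tracing`
captures the free-rider limit where an individual hospital's tracing
cannot move the resistance time line ($L_p(\gamma) = L_p(\gamma_0)$, so
$B \equiv 0$) and nobody invests unilaterally.

## Policy analysis

A permanent subsidy $S$ paid per stewarding year enters the steward's
excess profit, $C_S(p) = (E_p(\gamma_0) - E_p(\gamma) - S)/(E_p(\gamma)
+ S)$ — the most literal reading of "paying those who engage in
stewardship"; whether it would also be paid in the evolved state the
model cannot see, since only excess profit enters the comparison. An
alternative `mode = "net_cost"` treats $S$ as a flat rebate outside the
cost base. Under negative feedback a small subsidy drags the unique
equilibrium up a little; under positive feedback any subsidy below the
threshold that closes the gap at $p = 0$ changes nothing at all.
`minimum_switching_subsidy()` computes that threshold pointwise —
$S(p) = (E_p(\gamma_0) - E_p(\gamma) - B(p)E_p(\gamma))/(1 + B(p))$,
maximized over $p$ — giving the smallest subsidy that makes stewardship
dominant.

`temporary_subsidy_outcome()` plays the one-year intervention: the
population adjusts under the subsidized game, then the subsidy vanishes
and dynamics resume on the original game. Under negative feedback the
population drifts back — no lasting effect; under positive feedback a
large enough one-off payment relocates the population across the
separatrix and the switch to $p = 1$ is permanent. Outcomes are
classified `regime_switch` only when the long run lands on a *different*
pre-intervention stable equilibrium; a moved equilibrium is a
`marginal_shift`. Belief formation is modelled only through these
dynamics — there is no explicit belief state.

`collective_optimum()` maximizes the per-manager value
$W(p) = p\,E_p(\gamma)L_p(\gamma) + (1-p)\,E_p(\gamma_0)L_p(\gamma_0)$
that a cartel able to dictate actions would target, and
`externality_sign()` checks the precondition for the cartel to steward
more than Nash: $d(E_p(\gamma)L_p(\gamma))/dp > 0$, estimated by central
differences (step $10^{-5}$, one-sided and flagged at the boundaries,
zero band $10^{-9}$). The cartel optimizes the stewarding fraction at a
fixed action pair, matching the binary-choice frame; jointly optimizing
a continuous $\gamma$ per manager is an extension hook, not implemented.

## Numerical choices, problem sizes, and limits

* Continuous optimization (`optimal_action()`) is grid search (1001
  points) plus golden-section refinement to $10^{-8}$ in $\gamma$,
  because tabulated curves make $V(\gamma)$ piecewise linear and
  possibly multimodal; derivative-based methods are deliberately
  avoided. Tests compare against $10^5$-point dense-grid oracles.
* `critical_discount_factor()` uses the closed form
  $\delta^* = c/(\kappa_\gamma - \kappa_{\gamma_0} + c\,\kappa_\gamma)$
  and is cross-checked against bisection to $10^{-10}$; infeasibility is
  decided by the $\delta \to 1$ limit
  $(\kappa_\gamma - \kappa_{\gamma_0})/(1 - \kappa_\gamma) \le c$.
* Monte Carlo validation runs $10^5$ replicates per $(\delta, \kappa)$
  cell on a $3\times3$ grid and asserts agreement with $E \cdot L$
  within three standard errors; property suites use 100–200 random
  scenarios per invariant. These sizes keep the full suite under a
  minute while leaving the stochastic checks well-powered.
* The comparative-statics sweeps treat their three known monotonicity
  directions as internal consistency assertions: a violation raises an
  error rather than returning a report, since for stewardship actions
  ($\kappa(\gamma) \ge \kappa(\gamma_0)$) the directions are theorems,
  not hypotheses.

What the synthetic fixtures do *not* capture: gradual (multi-year)
resistance evolution — the regime shift is instantaneous by
construction; pest genetics and spatial structure behind $\kappa$;
manager heterogeneity; more than two evolutionary states; and societal
welfare beyond the managers' own profits. Passing tests therefore
demonstrate the decision calculus, equilibrium logic and policy
comparative statics of the model — not that any particular crop,
hospital or fishery satisfies its assumptions. Estimating $\Pi$,
$\bar\Pi$ or $\kappa$ from field data is out of scope; the package
consumes those inputs, it does not produce them.
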