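Package: evomanage
Title: Economic Decision Analysis for Managing Resistance Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding when costly stewardship of a biological
    resource (Bt crop refuges, antibiotic partner drugs, contact tracing)
    pays for itself by delaying adverse evolution. Models evolution as an
    irreversible regime shift from a pristine to an evolved state, combines
    economic discounting with annual persistence of efficacy into an
    effective life span, and evaluates the evolution management inequality:
    stewardship is beneficial when the percentage gain in effective life
    span exceeds the percentage of annual excess profit forgone. Includes
    single-manager optimization with critical discount factors, a
    population game for interacting managers with Nash equilibria and
    convergence stability, subsidy and cartel policy analysis, a Monte
    Carlo regime-shift simulator (including a reversible two-state
    variant), a catalog of worked-example fixtures, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
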