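Package: daphniahybrid
Title: Seasonally Forced Dynamics of Hybrid Establishment in Daphnia
    Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Deterministic simulator of interspecific hybrid establishment in
    cyclically parthenogenetic Daphnia communities. Six genotype classes (two
    parental species, F1 and F2 hybrids, and both backcrosses) are tracked as
    asexual females, sexual females, and dormant eggs (ephippia) under a
    seasonally forced logistic competition model with episodic switching to
    sexual reproduction, spring hatching from the dormant egg bank, an
    assortative-mating encounter kernel, class-specific overwintering
    performance, and Q10 temperature scaling of growth. Includes scenario
    builders for alternative parental growth-rate regimes, a piecewise ODE
    integrator aware of forcing discontinuities, annual summary statistics
    (abundances, proportions, establishment, dominance, persistence), and a
    bisection search for the growth-rate reduction that still permits hybrid
    persistence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
NeedsCompilation: yes
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
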