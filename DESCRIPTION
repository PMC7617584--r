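Package: distressim
Title: Dynamic Microsimulation of Tax-Benefit Policy and Psychological Distress
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale dynamic, stochastic, discrete-time microsimulation of
    the UK working-age population for contrasting the observed COVID-19-era
    tax and social security response (Universal Credit uplift, job retention
    scheme) against a pre-crisis counterfactual.  Generates a synthetic
    household-structured population, converts gross to disposable income under
    parametric policy systems, determines labour supply by discrete-choice
    random utility in normal years and by multinomial-logit state transitions
    in 2020-2021, and projects GHQ-12 psychological distress through a
    two-step process with additive effects of economic transitions.  Paired
    scenario runs with common random numbers and coefficient bootstrapping
    yield ranked uncertainty intervals for employment, poverty, distress
    prevalence, income and inequality outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics, grDevices, MASS, yaml
Suggests: testthat (>= 3.0.0), jsonlite, optparse, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
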