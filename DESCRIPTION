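Package: tendonadapt
Title: Multi-Scale Stochastic Simulation of Achilles Tendon Remodeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates geometric adaptation of the human Achilles tendon as the
    outcome of stochastic damage and repair acting on a population of collagen
    fibers. A discretized fiber-recruitment model gives the tendon its nonlinear
    force-extension behavior; per-fiber mechanical fatigue (S-N curve with an
    exponential cumulative-failure function) and strain-shielded proteolytic
    degradation remove fibers, and biased triangular repair distributions
    restore them longer (after fatigue) or shorter (after proteolysis). The
    tendon is embedded in a Hill-type Achilles-soleus musculotendon unit driven
    by a walking gait cycle; the metabolic cost of muscle activation feeds back
    on load intensity so that mean tendon length and fiber-length dispersion
    remodel toward a dynamic equilibrium. Includes tools for metabolic cost
    surface sweeps, multi-day remodeling trajectories, collagen turnover-time
    accounting, geometry-domain stability exploration and normalized parameter
    sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
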