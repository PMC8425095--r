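Package: beebreedsim
Title: Stochastic Simulation of Honeybee Breeding Schemes with Direct and
    Maternal Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte Carlo simulation of a closed honeybee (Apis mellifera)
    breeding program in which colony performance is the sum of the queen's
    maternal genetic effect, the mean direct genetic effect of the worker
    group, and a non-heritable residual. Breeding values follow an
    infinitesimal model with Mendelian sampling variance reduced by the
    dam's inbreeding. Inbreeding is tracked with a haplodiploid numerator
    relationship (coancestry) matrix built by a tabular method analogous to
    the X-linked case, validated against gene dropping. The annual cycle
    covers reproduction, winter mortality, phenotyping, mass or
    within-maternal-line selection of breeding queens, two-step selection
    of drone-producing queens, and mono- or polyandrous mating. Closed-form
    expressions for the initial phenotypic variance and heritabilities as a
    function of the polyandry level are provided, together with a scenario
    runner that aggregates per-year population statistics over replicates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
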