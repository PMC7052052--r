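Package: mmcsim
Title: Multiple-Merger Coalescent Simulation from Cannings Models with
    Fluctuating Population Size
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the discrete genealogies of modified Moran models with
    skewed offspring numbers and of heavy-tailed Cannings models under
    deterministic population-size change, together with their exact
    multiple-merger (Lambda-) n-coalescent limits under the induced
    deterministic time change. Provides Lambda-measure merger-rate tables,
    offspring-law constructors (including rarefied sweepstake reproduction),
    population-size profiles and their backward-in-time discretisations,
    Gompertz waiting-time closed forms under exponential growth, a mutation
    overlay, and Monte-Carlo diagnostics that check the discrete models
    against their coalescent limits (coalescence-probability scaling,
    Moehle-Sagitov ratios, time-scale tables, and distributional tests on
    simulated genealogies). Genealogies are exportable as Newick text and
    tabular event lists.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
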