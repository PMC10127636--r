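Package: antagosim
Title: Multi-Antagonist Effects on Competitive Microbial Communities
Version: 1.0.0
Authors@R: person("antagosim", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates how multiple antagonists (phages, plasmids and other
    mobile genetic elements) jointly affect the composition of a competitive
    microbial community. Assembles random competitive Lotka-Volterra systems
    with an antagonist layer, integrates them to their long-run state with an
    adaptive Runge-Kutta 5(4) scheme, and scores paired with/without-antagonist
    equilibria by Bray-Curtis dissimilarity and Kendall rank correlation over
    Monte-Carlo parameter sweeps. Includes closed-form half-normal moments,
    the coefficient of variation of combined antagonist effects, Shannon
    diversity and Pielou evenness, a reproducible counter-based seeding
    scheme, CSV/JSON serialization and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
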