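Package: nitrofate
Title: Redox-Constrained Chemostat Modelling of Anaerobic Nitrogen Cycling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates competition between the anaerobic nitrogen-cycling
    microbial functional types (heterotrophic denitrification resolved as two
    single-step populations, dissimilatory nitrite reduction to ammonium, and
    chemoautotrophic anammox) in a virtual chemostat. Metabolic budgets are
    generated from electron, carbon, and nitrogen balances of the underlying
    half reactions; biomass yields, subsistence concentrations (R*), and
    consumption vectors follow from the budgets; steady states are obtained by
    stiff ODE integration. Analysis tools classify competitive regimes across
    organic-matter to nitrite supply ratios, partition the fate of nitrite,
    and locate the supply ratio of net zero nitrogen loss, where ammonium
    regeneration by nitrite ammonification balances dinitrogen production.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
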