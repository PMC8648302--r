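Package: mesoflux
Title: Mesophyll Conductance and Membrane CO2 Permeability Analysis for C4 Leaves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis chain for studies of mesophyll CO2 diffusion in
    C4 plants. Implements the enzyme-limited C4 photosynthesis model and its
    closed-form link between mesophyll conductance (g_m) and the initial slope of
    the A-Ci curve; estimation of g_m from coupled gas-exchange and C18O16O
    discrimination records under full isotopic equilibrium, with a carbonic
    anhydrase limited correction; stopped-flow estimation of membrane CO2
    permeability in single cells; and freeze-thaw survival quantification from
    plate-reader growth curves as percent area under the curve. Every estimator is
    paired with a forward simulator so the whole chain is validated by parameter
    recovery at known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    minpack.lm,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
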