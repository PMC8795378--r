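Package: ldpsim
Title: Light-Distribution Surrogate Models for Semi-Continuous Algal
    Cultivation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Machine-learning-informed modelling of light availability and
    growth in cyanobacterial cultures. Provides a physics-based generator of
    two-dimensional light distribution patterns (LDPs) inside photobioreactors
    and ponds, pixel-wise support-vector-regression surrogates that predict
    full LDPs from incident light intensity and cell concentration, a
    growth-rate model driven by LDP features, a coupled iterative growth
    simulator for optimizing semi-continuous cultivation schedules, and
    harvest analytics (optical density to dry cell weight conversion, solids
    content, Stokes settling, aggregation and adherence fractions).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    png,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
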