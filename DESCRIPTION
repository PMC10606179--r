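Package: thinlayer
Title: Thin-Layer Drying Kinetics, Moisture Diffusivity and Carotenoid
    Degradation Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for thin-layer hot-air drying experiments on
    slab-shaped plant material such as tomato peels. Converts weighed drying
    curves to dimensionless moisture ratios, estimates effective moisture
    diffusivity from the Fick slab solution by linearized regression,
    fits the temperature dependence of diffusivity with an Arrhenius law to
    obtain the activation energy, fits and ranks ten classical thin-layer
    drying models (Newton, Page, Modified Page, Henderson-Pabis, Midilli,
    Logarithmic, Two-term and others) by nonlinear least squares, computes
    specific drying-energy requirements, and models the thermal degradation
    of carotenoids (lycopene, beta-carotene) with drying temperature.
    Includes a finite-difference solver of the one-dimensional diffusion
    equation as an independent check on the series solution, and seeded
    synthetic-data generators for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
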