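Package: lcdcc
Title: Consistent Competitive Ligand and Charge Distribution Modeling of
    Natural Organic Matter Adsorption to Goethite
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic simulation of the simultaneous (competitive)
    adsorption of humic acid (HA) and fulvic acid (FA) particles to goethite
    with the consistent competitive Ligand and Charge Distribution (LCD_cc)
    framework. Couples CD-MUSIC multi-plane surface speciation and
    electrostatics of the goethite-water interface, bimodal NICA proton
    binding of NOM functional groups, an ADAPT-style variable median
    adsorption affinity, competitive Langmuir-Freundlich partitioning with
    particle-level heterogeneity, interfacial (Stern/d-plane) charge and
    ligand distributions, adsorptive molecular-mass fractionation, and
    constant- versus variable-adsorption-volume scenarios. Includes the
    batch-design simulators, exchange-ratio and RMSE evaluation, sensitivity
    sweeps, and a deterministic synthetic-isotherm generator with a
    parameter-recovery harness.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
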