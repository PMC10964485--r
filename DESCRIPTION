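Package: ferrokin
Title: Kinetics of Anaerobic Fe(III) Bioreduction by Acidophilic Consortia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing ferric iron bioreduction kinetics in stirred
    tank reactors operated with acidophilic microbial consortia. Provides
    Nernst-based iron speciation from redox potential, batch rate estimators
    (maximal and mean Fe(II) production rates), fitting of the linear
    biomass-rate law, exact stoichiometric balancing of the reductive
    bioleaching reactions including biomass nitrogen demand, mass-balance
    simulators for batch reactors and a two-stage growth/bioreduction
    chemostat cascade, nutrient consumption flux accounting, and a seeded
    synthetic-data generator for end-to-end parameter recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'ferrokin-package.R'
    'constants.R'
    'rational.R'
    'AllGenerics.R'
    'AllClasses.R'
    'speciation.R'
    'rates.R'
    'stoichiometry.R'
    'reactors.R'
    'nutrients.R'
    'synthetic.R'
    'io.R'
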