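Package: kieflux
Title: Kinetic Isotope Effects in Kinetic and Isotopic Models of Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates isotope labeling experiments on kinetic models of
    metabolic networks while accounting for kinetic isotope effects (KIEs).
    Reaction rate laws are decomposed into unidirectional components, every
    combination of substrate isotopomers of every component defines a fluxomer,
    and the isotopomer balance system dI/dt = U (f o a) couples the kinetic and
    isotopic layers through a sparse incidence matrix U and a vector a of KIE
    fractionation factors. Provides network parsing and validation, isotopomer
    and fluxomer enumeration, stiff ODE integration to isotopic steady state,
    derived observables (isotopomer and isotopologue distributions, molecular
    enrichments, unidirectional and net fluxes), with/without-KIE impact
    reports, an exchange-free model variant, and global sensitivity analysis
    over enzyme levels. Ships a fully parameterized toy network and the
    structure of the Escherichia coli glycolysis/pentose-phosphate network
    with published 13C fractionation factors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    deSolve,
    dplyr,
    tibble,
    rlang,
    generics,
    ggplot2,
    readr,
    yaml,
    jsonlite,
    xml2,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
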