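Package: cardioflux
Title: Flux-Minimization Analysis of Cardiomyocyte Substrate Utilization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Constraint-based simulation of cardiomyocyte energy metabolism:
    flux-balance analysis with a two-stage flux-minimization objective
    (substrate plus oxygen uptake, then total flux), simplex-grid scanning of
    substrate compositions under uptake-coupling constraints, alternate-optima
    enumeration with flux-uniqueness statistics, and a Euclidean
    ideal/anti-ideal (TOPSIS-style) efficiency index for ranking substrate
    supplies. Includes a generator for a reduced cardiomyocyte core network
    with literature ATP/O2 substrate yields, a glycogen store, phospholipid
    synthesis targets with essential fatty acids, and an NADPH branch, plus
    SBML and native JSON model input/output and metabolic-function
    feasibility testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    xml2
Suggests:
    boot,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
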