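Package: fqchelate
Title: Fluoroquinolone-Metal Chelation Pharmacokinetics and QSPR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the interaction between oral fluoroquinolone
    antibiotics and multivalent metal cations (aluminum, magnesium, calcium).
    Implements one-compartment oral absorption kinetics (Bateman curves,
    inversion of the Tmax equation for the absorption rate constant), terminal
    slope extraction of elimination parameters from concentration-time data,
    physicochemical descriptors from SMILES (monoisotopic mass, Ertl
    topological polar surface area with N/O/S/P polar atoms, Wildman-Crippen
    logP), stoichiometric bookkeeping of chelation binding energies from
    quantum-chemistry energy ledgers, construction of octahedral bidentate
    chelate starting geometries, and the linear structure-property regressions
    relating bioavailability reduction to descriptors and binding energies.
    Includes a synthetic-data module generating pharmacokinetic interaction
    studies with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
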