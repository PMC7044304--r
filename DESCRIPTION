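Package: npncaps
Title: Discovery and Quantification of Dinucleoside Polyphosphate RNA Caps from LC-MS Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying and quantifying dinucleoside polyphosphate
    (NpnN) 5'-RNA caps from high-resolution LC-MS peak lists. Provides an
    exact monoisotopic mass and adduct engine validated against published
    high-resolution reference values, enumeration of candidate cap ion
    libraries, ppm-tolerance peak annotation with digestion-negative-control
    filtering, nitrogen counting from paired 14N/15N metabolic labelling runs,
    rule-based in-source and MSn fragment prediction for discriminating
    internal-bridge caps from terminal polyphosphate isomers, and quantitative
    readouts (standard-addition calibration, relative EIC abundance, decapping
    assay classification, gel densitometry percentages and first-order
    cleavage kinetics). A seeded synthetic-data generator emulates every input
    the pipeline consumes so all stages are testable end to end.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
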