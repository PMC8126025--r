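Package: ffeprof
Title: Membrane Profiling from Free Flow Electrophoresis Fractionation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse quantitative protein profiles from free flow
    electrophoresis (FFE) membrane fractionation experiments. Pools raw FFE
    fractions into analysis samples, normalizes SWATH-style peak areas to the
    per-fraction protein amount (OD280), averages biological replicates into
    per-protein "digital western" profiles, builds compartment consensus
    profiles from curated marker proteins, assigns proteins to subcellular
    compartments by profile correlation, detects one- versus two-population
    (candidate dual-localized) profiles, flags disagreement with prior
    annotation, and summarizes transmembrane-domain predictions. Includes a
    synthetic FFE-run generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
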