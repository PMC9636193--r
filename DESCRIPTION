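Package: metanno
Title: Multilayer-Network Metabolite Annotation for Untargeted LC-MS/MS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Annotates untargeted LC-MS/MS metabolomics features by propagating
    identifications from confidently matched seed metabolites across a metabolic
    reaction network that has been expanded from known metabolites into predicted
    unknowns via biotransformation rules. Candidate features are accepted under
    four constraints (reaction pairing, MS1 m/z, predicted retention time, MS/MS
    similarity against surrogate seed spectra), ion forms (isotopes, adducts,
    neutral losses, in-source fragments) are deconvolved through a global peak
    correlation network with explicit conflict resolution, and annotations are
    scored and reported with MSI-style confidence levels. Includes a synthetic
    data generator with planted ground truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tools,
    tidyr,
    utils,
    yaml
Suggests:
    ChemmineR,
    withr,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
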