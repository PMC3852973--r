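Package: domainmapr
Title: Protein Domain Architecture from Limited Proteolysis and SEC-SLS
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Maps the rigid-domain / flexible-linker architecture of
    multi-domain proteins from solution experiments. Identifies limited
    proteolysis fragments by matching Edman N-terminal reads and intact
    masses against in-silico protease digests, assembles the persistent
    fragments into a domain map, and classifies construct flexibility,
    oligomeric state and pairwise interaction from gel-permeation
    chromatography (GPC), static light scattering (SLS) and bio-layer
    interferometry (BLI) data. Includes a ground-truthed synthetic-data
    generator so the whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
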