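Package: nrekit
Title: N-Terminal Regulatory Elements of Plant Receptor-Like Kinases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Extraction and analysis of the N-terminal regulatory element
    (NRE) of plant receptor-like kinases: topology classification into
    receptor kinases and receptor-like cytoplasmic kinases with or without
    a transmembrane helix, kinase-domain boundary refinement with the
    (L/I/V)GXG anchor, juxtamembrane and N-terminal kinase extension
    extraction, length and position-scaled composition profiling, sequence
    logos, detection of the conserved 14-residue C-terminal consensus and
    ST motif, ZOOPS expectation-maximisation motif discovery, position
    weight matrix scanning with exact p-values computed by dynamic
    programming, class enrichment via the normalized-frequency statistic,
    phosphosite-motif containment and conservation tiers, and a
    ground-truthed synthetic dataset generator.
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    knitr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
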