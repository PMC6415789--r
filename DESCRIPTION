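Package: siplabel
Title: Identification of Isotope-Labelled Taxa in DNA Stable Isotope
    Probing Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical screening of amplicon count data from DNA stable
    isotope probing (SIP) experiments. Per-taxon odds ratios between heavy
    and light buoyant-density fractions are compared between the 12C control
    and 13C labelled incubations with the Breslow-Day test for homogeneity
    of odds ratios, and family-wise error is controlled with the
    Holm-Bonferroni step-down procedure. Includes readers and writers for
    mothur-style OTU tables, a truth-tagged synthetic SIP experiment
    generator built on a CsCl buoyant-density gradient model, fluorometric
    enzyme assay processing with per-gene-copy normalisation, and microcosm
    carbon budget arithmetic.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
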