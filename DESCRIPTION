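Package: exoprofiler
Title: Exonuclease-Protection Profiling of Aptamer-Ligand Binding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis of exonuclease-protection fluorescence
    assays for profiling aptamer-small-molecule binding. Generates synthetic
    digestion and strand-displacement time courses with ligand-dependent
    protection, computes AUC-based resistance values and cross-reactivity
    profiles, calls binders in candidate screens, and estimates apparent
    binding affinity from resistance dose-response series.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    rlang,
    stats,
    pracma,
    minpack.lm,
    Biostrings
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
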