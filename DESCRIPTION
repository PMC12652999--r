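Package: anapquench
Title: Fluorescence Quenching Analysis for ANAP-Based Neurotransmitter Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for measuring serotonin and dopamine binding via
    collisional quenching of the fluorescent non-canonical amino acid ANAP.
    Implements steady-state Stern-Volmer analysis with inner-filter correction,
    instrument-response-function (IRF) reconvolution fitting of time-resolved
    photoluminescence and transient-absorption decays, and bleach-corrected
    Hill concentration-response analysis of receptor-bound ANAP fluorescence,
    together with seeded synthetic-data generators that emulate every input so
    the whole pipeline is verifiable by parameter recovery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    signal,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
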