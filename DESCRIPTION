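Package: flavomix
Title: Chlorophyll Fluorescence and Multi-Omics Screening of UV-B Flavonoid
    Responses
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for studies of UV-B stress and
    exogenous abscisic acid (ABA) in plants, built around a three-group
    (PAR control, UV-B, UV-B + ABA) replicated design. Implements PAM
    chlorophyll fluorescence parameters (Fv/Fm, Y(II)) with ANOVA/Tukey
    compact-letter summaries; the JIP-test for fast fluorescence induction
    (OJIP) transients, including Vt/Wt double normalizations and
    treatment-minus-control difference curves with J-step and K-band
    statistics; a from-scratch two-class OPLS-DA (NIPALS) with
    cross-validated Q2 and VIP scoring; differential-metabolite and
    differential-gene screening by VIP/fold-change and q-value/fold-change
    rules; hypergeometric pathway over-representation with
    Benjamini-Hochberg adjustment; and signed Pearson correlation networks
    between metabolites, transcripts and transcription-factor genes. A
    synthetic-data generator with planted ground truth emulates the full
    study design so every stage is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
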