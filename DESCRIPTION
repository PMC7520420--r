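Package: adcpkpd
Title: Translational Pharmacokinetic-Pharmacodynamic Modeling of
    Antibody-Drug Conjugates
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for translational PK/PD analysis of HER2-targeted
    antibody-drug conjugates (ADCs): two-compartment linear IV
    pharmacokinetics with allometric interspecies scaling, a
    transit-compartment tumor-growth-inhibition (TGI) model for mouse
    xenograft studies, tumor-static-concentration (TSC) derivation with
    parametric-bootstrap confidence intervals, a target-mediated drug
    disposition (TMDD) model with shed antigen for clinical PK,
    non-compartmental analysis, two-stage parameter estimation with fit
    diagnostics, synthetic-study generation, and mouse-to-human efficacy
    translation with outcome classification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
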