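Package: gabaflux
Title: Constraint-Based Flux Analysis for GABA and Butyrolactam Strain Design
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Stoichiometric metabolic modeling toolkit for model-guided
    design of GABA- and butyrolactam-producing Corynebacterium glutamicum.
    Provides flux balance analysis (FBA) with parsimonious canonicalization
    and flux variability analysis on a built-in two-phase simplex solver,
    producer-mode optimization under a biomass floor, aconitase
    flux-multiplier scans with normalized flux-change matrices,
    double-robustness surfaces over growth and TCA-cycle fluxes, and
    in-silico emulation of knockout/overexpression strain series. Ships a
    carbon-balanced synthetic core-carbon model of C. glutamicum (EMP, PPP,
    TCA cycle, glyoxylate shunt, anaplerosis, glutamate decarboxylase route,
    GABA shunt and transport, acetyl-CoA-dependent butyrolactam branch)
    together with small oracle-verifiable fixture models and an exhaustive
    LP vertex-enumeration oracle for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    boot,
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
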