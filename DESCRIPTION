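Package: bifacet
Title: Design and Screening Analytics for Bifaceted Cytokine Receptor Antagonists
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to design and characterize single-domain, bifaceted
    antagonists of homodimerizing type I cytokine receptors such as G-CSFR.
    Provides pseudosymmetric binding-site grafting on four-helix bundles with
    register optimization and binding-site backbone RMSD assessment (Kabsch
    superposition), inter-transmembrane-domain spacing of ternary complex
    models, combinatorial two-fragment oligo-pool library accounting with
    FACS gate and coverage math, plate-screen Z-scores and consensus logos,
    1:1 Langmuir surface plasmon resonance kinetic simulation and global
    fitting with double referencing and leave-one-out statistics,
    four-parameter logistic dose-response (EC50/IC50) estimation, dual-color
    single-molecule co-tracking and mean-squared-displacement diffusion
    analysis, and seeded synthetic-data generators for every input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings
Config/testthat/edition: 3
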