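Package: oxphos
Title: Mitochondrial Bioenergetic Diagnostics from Respirometry, Fluorometry, Imaging and Proteomics
Version: 0.1.0
Authors@R:
    person("Open", "Bioenergetics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comprehensive mitochondrial diagnostics in cells and isolated
    mitochondria: creatine-kinase (CK) clamp thermodynamics (binding-polynomial
    speciation, apparent equilibrium constants, clamped ATP free energy across
    phosphocreatine titrations), chamber respirometry trace analysis (oxygen flux,
    steady-state extraction, non-mitochondrial correction, normalization, FCCP Km),
    derived oxidative-phosphorylation statistics (JH+ total, JH+ OXPHOS, fractional
    OXPHOS, FCCP effect, P/O ratio, OXPHOS power output), fluorometric NADH redox and
    TMRM membrane-potential calibration (Nernst/KCl), confocal z-stack signal-volume
    quantification with Huang auto-thresholding, and TMT isobaric-label proteomics
    normalization with BH-FDR differential expression. A synthetic-data module
    generates every input modality with known ground truth so the full pipeline is
    testable offline.
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
    optparse,
    withr
Config/testthat/edition: 3
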