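Package: fragscore
Title: Fragment-Based Scoring and Evaluation of Predicted Protein
    Interface Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for discovering and validating domain-motif and
    domain-domain interfaces from protein structure-prediction outputs.
    Reads predicted complex models (PDB, with per-residue pLDDT in the
    B-factor field) and score bundles (ipTM/pTM/PAE), designs sliding-window
    fragments of disordered regions and fragment-extension schedules,
    computes interface confidence metrics (interface pLDDT variants, model
    confidence, pDockQ, iPAE, contact counts), evaluates models against
    native reference structures (domain-frame superposition, all-atom motif
    RMSD with accuracy categories, DockQ), builds positive and random
    benchmark sets (Miyata-distance mutagenesis, cognate-avoiding shuffles),
    derives ROC/PR statistics and optimal cutoffs, and analyses BRET
    titration experiments (corrected BRET, detection calls, hyperbolic
    saturation-curve fits for BRETmax and BRET50).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    graphics
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
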