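Package: coftools
Title: Binding-Site Geometry, Residue Screening and Assay Quantification
    for CofC/CofD F420 Biosynthesis Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for studies of the guanylyltransferase CofC/FbiD
    and its partner CofD/FbiA in coenzyme F420 biosynthesis. Provides PDB
    parsing and binding-site geometry (out-of-pi-plane hydrogen-bond
    distortion, ligand contact tables, Kabsch superposition, carboxylate
    rotation angles, magnesium coordination audits), diagnostic-residue
    screening of CofC homolog alignments (Needleman-Wunsch identity, residue
    to alignment-column mapping, serine/threonine specificity calls),
    quantification of combined CofC/D activity assays (extracted ion
    chromatograms, peak integration, linear-range rate fits, relative
    turnover profiles), two-state thermal-unfolding fits with ligand linkage
    for nano-DSF dissociation constants, and seeded synthetic-data
    generators with machine-readable ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    minpack.lm,
    stats,
    utils
Suggests:
    bio3d,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
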