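Package: idrg
Title: Identify Intrinsically Disordered Segments in Protein Complexes
    from Bound-State Geometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Structure-based detection of intrinsically disordered (ID)
    protein segments captured in complex with globular partners.  A chain is
    scored by its radius of gyration per residue (Rg/N^nu) computed over
    alpha-carbon coordinates; extended ID segments score high and compact
    globular chains score low, so a simple threshold (0.26 Angstrom at
    nu = 1) separates the two classes.  The package also provides Flory
    scaling-law fits (Rg = R0 * N^nu), Shrake-Rupley solvent-accessible
    surface area with delta-SASA interface detection and core/rim/support
    classification, geometric salt-bridge, hydrogen-bond and disulfide
    detection with per-area normalisation, dataset-curation filters
    (length gates, disulfide-rich exclusion, Rost-curve redundancy
    clustering), classifier evaluation (ROC/AUC, Matthews correlation,
    half-sample resampling), synthetic structure generators for testing,
    and a batch scanning pipeline with a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    Biostrings,
    optparse
Config/testthat/edition: 3
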