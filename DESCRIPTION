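Package: ppiprop
Title: Protein-Protein Interface Propensity Analysis and Patch-Based
    Interface Residue Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of protein-protein interfaces and
    patch-based interface residue prediction from single (unbound)
    domains. Computes solvent accessible surface areas (Shrake-Rupley),
    extracts interfaces from partitioned complexes (delta-ASA and
    cross-chain contact criteria), and derives relative interface ratios
    (RIR) of residue types, secondary structure states, 60 combined
    classes and per-type ASA classes, together with inter-chain residue
    contact frequencies and preferences and interface size statistics.
    Ships the quantitative interface propensity index (QIPI) and
    implements the SPR (Single domain based Patch Recognition)
    predictor: surface patch growing and merging with distance-binned
    ASA thresholds, a four-term empirical scoring function (residue
    propensity, hydrophobicity, conservation from PSI-BLAST profiles,
    solvation), weight training by maximizing coverage x accuracy, and
    k-fold cross-validation. Includes a deterministic synthetic-complex
    generator so the full pipeline runs without external data.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
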