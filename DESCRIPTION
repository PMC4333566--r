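Package: memqc
Title: Quality Metrics for Membrane-Transporter Structural Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assessment toolkit for homology models of polytopic membrane
    transporters. Computes per-residue hydrophobic-conservation profiles from
    multiple sequence alignments, consensus transmembrane topology from
    multiple predictor tracks, trajectory-based model-quality statistics
    (Kabsch superposition RMSD, hydrogen-bond based secondary-structure
    assignment and helicity conservation, binding-cavity volume, ligand
    contact occupancy, salt-bridge occupancy, area per lipid), and
    variable-slope sigmoidal fits of competition radioligand-binding data
    (pIC50). Ships deterministic synthetic-data generators so the full
    pipeline is testable at desk scale without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
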