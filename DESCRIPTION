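Package: ptmstructkit
Title: Structural Characterization of Post-Translational Modification Sites
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Toolkit for analysing post-translational modification (PTM)
    substrate sites on protein three-dimensional structures. Maps modified
    peptides onto PDB chains at 100% sequence identity, detects sequentially
    and spatially neighboring residues, computes side-chain orientation
    angles and classifies functional residues, profiles radial amino-acid
    composition around substrate sites, computes solvent-accessible surface
    area by the Shrake-Rupley method, screens PTM sites for proximity to
    bound drug-like ligands, builds non-homologous positive/negative
    benchmark datasets for PTM-site predictors with redundancy reduction and
    cross-set purging, evaluates predictor output (Sn, Sp, Acc, MCC), and
    assembles PTM regulatory networks from pathway membership and
    protein-protein interaction tables. Ships a deterministic synthetic-data
    generator so every component is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
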