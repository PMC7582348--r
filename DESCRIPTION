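Package: gpcrtraj
Title: Transmembrane Rotation, Contact and Consensus-Pharmacophore Analysis for GPCR Simulations
Version: 0.1.0
Authors@R: person("gpcrtraj", "developers", role = c("aut", "cre"), email = "dev@example.org")
Description: Analyses of 7-transmembrane (7-TM) receptor trajectories and
    antagonist docking poses: per-helix rotation angles against a reference
    frame, hydrogen-bond / hydrophobic / salt-bridge contact tables and
    arginine-cage tracking, inter-chain centre-of-mass distance series,
    GROMOS conformational clustering with representative frames,
    Ramachandran summaries, docking-pose clustering at an RMSD cutoff, and
    consensus pharmacophore models built by typing ligand features and
    clustering them with a deterministic partition-around-medoids method,
    annotated with receptor residues within 5 Angstroms. A synthetic-data
    module generates 7-TM bundles, receptor-chemokine complexes and ligand
    pose libraries with planted ground truth so every stage is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: jsonlite, stats, utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
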