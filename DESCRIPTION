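Package: choltraj
Title: Cholesterol and Ligand Contact Analysis for Membrane-Protein Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Trajectory analysis toolkit for membrane proteins of the TSPO
    (translocator protein) family. Scans protein sequences for cholesterol
    recognition motifs (CRAC, CARC, CRAC-like, GXXXG, WXPXF, LAF), computes
    distance-cutoff cholesterol contact and occupancy statistics per
    transmembrane helix with a simultaneous-versus-bridging classification of
    paired motif occupancy, derives per-residue ligand interaction fingerprints
    with constant/frequent binder classes and a distance-criterion hydrogen
    bond occupancy, and provides structural stability metrics (Kabsch
    superposition, RMSD, RMSF, coordinate PCA, and sliding-window helix
    bend-angle profiles). A synthetic membrane-protein trajectory generator
    with exact ground truth supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
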