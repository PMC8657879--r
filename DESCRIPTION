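Package: foldcv
Title: Residue Folding Degree and Secondary-Structure Collective Variables
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes the residue folding degree, a weighted
    subgraph-centrality measure on the protein backbone dihedral graph,
    from PDB structures and multi-model trajectories, by both the full
    spectral formulation and a fast 4x4 block approximation.  Provides
    the relative segment folding degree, a bounded collective variable
    that quantifies alpha-helical content or similarity to an arbitrary
    reference conformation along molecular-dynamics trajectories,
    together with secondary-structure category statistics (DSSP, DSSP 4
    and STRIDE label parsing, agreement matrices, motif-length
    histograms), potential-of-mean-force surfaces from collective
    variable time series, and minimax minimum-energy paths with barrier
    heights.  Includes deterministic synthetic-data generators (backbone
    reconstruction from internal coordinates, random dihedral ensembles,
    two-state switching trajectories) and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    stats,
    utils
Suggests:
    Matrix,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
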