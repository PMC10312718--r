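Package: voxtrace
Title: Voxel-Labeled Cryo-EM Density Maps and HMM-Guided Backbone Tracing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to turn cryo-EM density maps into standardized,
    voxel-labeled training volumes and to trace protein backbones through
    predicted carbon-alpha voxels. Reads, writes and validates MRC2014
    volumes; resamples maps to a uniform 1 Angstrom grid and normalizes
    densities to [0, 1] by the positive-value 95th-percentile rule; converts
    atomic structures into per-voxel atom, carbon-alpha, amino-acid and
    secondary-structure masks with a coordinate round-trip verifier; divides
    maps into overlapping sub-grids and stitches predictions back; threads a
    protein sequence through candidate carbon-alpha voxels with a hidden
    Markov model whose Gaussian-distance transitions and geometric-mean
    emissions are searched by a use-each-state-at-most-once Viterbi beam
    search; scores voxel predictions (precision/recall/F1) and compares
    reconstructed backbones to reference structures (matching percentage,
    sequence identity, RMSD). A synthetic-data generator produces toy
    backbones, simulated density maps, ground-truth masks and corrupted
    prediction volumes so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    seqinr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
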