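Package: helixdimer
Title: Geometric Descriptor Analysis of Transmembrane Helix Dimer Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-frame geometric descriptors for two-helix transmembrane
    dimers from coarse-grained or atomistic trajectories: per-helix rotation
    angles about segmented local axes, signed crossing angle with packing
    handedness, lateral helix separation, the N/C-termini distance
    difference, dimerization-state classification, Boltzmann-inversion free
    energy landscapes over rotation-angle pairs, detection of pivoting
    motions and handedness interconversions, and interhelical residue-residue
    contact scoring with top-pair concordance. Includes a kinematic ideal
    helix-dimer generator for scripted trajectories with known ground truth,
    multi-model PDB and GRO readers/writers, and a reproducible
    generate/analyze/report pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
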