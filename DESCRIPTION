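Package: helixptm
Title: Helix-Pair Motif Geometry and Solvent Accessibility of
    Post-Translationally Modified Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the structural analysis of post-translationally
    modified (PTM) proteins. Reads and writes PDB coordinate files,
    assigns secondary structure by the Kabsch-Sander hydrogen-bond
    method, fits helix axes and computes the six pairwise descriptors of
    a helix-pair super-secondary motif (interplanar distance d, minimum
    axis distance r, torsion angle theta, planar angle phi, and the area
    S and perimeter P of the intersection of the projected helix
    strips), classifies alpha-alpha-corner versus L/V helix pairs,
    builds phosphorylation, acetylation and ubiquitylation-remnant
    moieties in silico, quantifies the solvent-accessible surface area
    (Shrake-Rupley) of the modified residue and its active environment,
    and analyses multi-model pseudo-trajectories (descriptor time
    series, Kabsch RMSD, GROMOS conformational clustering). A synthetic
    structure generator provides ideal helices, helix pairs with known
    geometry and noisy pseudo-trajectories for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    bio3d
Config/testthat/edition: 3
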