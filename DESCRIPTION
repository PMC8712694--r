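Package: poregate
Title: Hydrophobic Gating and Conformational Analysis of Hexameric Channel Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trajectory analyses for hydrophobically gated ion channels such as
    the hexameric CRAC/Orai channel: inscribed-sphere pore radius profiles with
    HOLE-style occupancy classification, region-resolved water counting and
    dewetting (bubble) detection, Boltzmann-inversion potentials of mean force
    (axial, radial-axial, and radius-rotation), Wimley-White hydrophobicity
    profiles, alpha-carbon based helix rotation angles at axial levels,
    Shrake-Rupley solvent accessible surface area, residue contact-event timing
    with six-fold subunit consensus, inter-helical distances with signed
    projected displacements, chi1 dihedral series, selection-based RMSD with
    block averaging, and targeted-MD schedule utilities. Includes a synthetic
    C6-symmetric channel generator that scripts gating motions (per-level helix
    twist, pore dilation, outer-helix bending, side-chain flips, pore
    dewetting) with exact ground truth for validating every analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
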