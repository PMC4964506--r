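Package: aquaflux
Title: Water Permeability and Residue Dipole Gating Analysis for Channel
    Protein Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trajectory-analysis toolkit for tetrameric water channels
    (aquaporin-like systems) under perpendicular electric-field pulses.
    Computes per-pore osmotic permeability via the collective diffusion
    model (collective coordinate n(t), its diffusion constant D_n and
    p_f = v_w * D_n), in-channel water self-diffusivity with a
    non-Fickian log-log exponent, discrete permeation events, residue
    dipole orientation (cos-theta) distributions and two-state flipping
    kinetics, heavy-atom RMSD rearrangement matrices, and the paired
    one-tailed t-test / one-way ANOVA statistical layer used to compare
    field conditions against the zero-field case. Includes a
    ground-truth-known synthetic trajectory generator (Brownian channel
    waters, telegraph-process residue dipoles, scripted rearrangements)
    so the whole pipeline is testable without molecular-dynamics output,
    plus PDB/DCD readers and writers for real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    nortest,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
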