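Package: bliscreen
Title: Fragment-Screen Triage for Biolayer Interferometry, STD-NMR and
    Mixed-Solvent Occupancy Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis chain for biosensor-based fragment screening against
    protein-protein interaction targets such as the N-domain of the AAA+
    ATPase p97. Simulates and preprocesses biolayer-interferometry (BLI)
    sensorgrams (double referencing, bracketing-control correction,
    steady-state quantification), computes screen quality statistics
    (Z-factor) and calls hits, fits 1:1 Langmuir and heterogeneous 2:1
    binding models globally across dilution series, performs k_obs
    linearity analysis, and combines plateau, curve-shape and k_obs
    evidence into a composite triage score. Also provides a ligand
    efficiency panel (LE, SILE, LELP, LLE_AT) with descriptor PCA,
    STD-NMR quantification (STD effects, exponential build-up initial
    rates, NOE R-factor) and HSQC chemical shift perturbation mapping,
    and voxel-occupancy analysis of solvent-probe trajectories (site
    discovery, binding-site residues, representative poses, OpenDX
    output). A synthetic-data module generates every input with the
    statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    bio3d,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
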