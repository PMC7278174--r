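Package: sumdlite
Title: Supervised Molecular Dynamics with a Coarse-Grained Langevin Engine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements the supervised molecular dynamics (SuMD)
    adaptive-sampling protocol for ligand-binding simulations together with a
    self-contained coarse-grained Langevin dynamics engine and synthetic
    receptor-ligand scenario generators (funnel pocket, charged vestibule,
    cryptic sub-pockets, explicit solvent beads). SuMD propagates short
    unbiased time windows and keeps only windows in which the ligand-to-site
    centroid distance trends downward (negative least-squares slope),
    restarting rejected windows with resampled velocities. A trajectory
    analysis suite provides per-residue electrostatic and van der Waals
    interaction-energy decomposition, ligand-site distance profiles,
    interaction-energy landscapes, RMSD/RMSF, grid-based pocket volumetry, and
    solvent-occupancy hotspot maps written as OpenDX grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    bio3d,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
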