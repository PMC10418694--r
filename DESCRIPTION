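Package: DXTracker
Title: Diffracted X-Ray Tracking of Single-Molecule Rotational Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for diffracted X-ray tracking (DXT) of
    membrane-protein rotational dynamics. Models the Bragg diffraction
    geometry of gold nanocrystal labels, detects and links diffraction
    spots in time-resolved detector movies into trajectories, converts
    spot motion into tilting (theta) and twisting (chi) angular
    trajectories, and quantifies ligand-dependent motion through
    ensemble mean-square-displacement fits, angular-displacement
    distributions, two-dimensional probability-density maps and
    two-condition difference maps. Includes a calibrated synthetic-data
    generator emulating agonist (carbamylcholine) and antagonist
    (alpha-bungarotoxin) conditions for the nicotinic acetylcholine
    receptor.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
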