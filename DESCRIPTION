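Package: mdensemble
Title: Conformational Ensemble Analysis and MM-GB(SA) Energetics for
    Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for conformational ensembles of proteins and
    protein-ligand complexes: structure and trajectory input/output (PDB, DCD),
    atom selections, superposition-based descriptors (RMSD, RMSF, radius of
    gyration, Shrake-Rupley solvent-accessible surface area, distances, angles,
    torsions, triangle areas, contact shells), hydrogen-bond and water-bridge
    occupancy, salt bridges, Kabsch-Sander secondary-structure timelines,
    essential dynamics (positional covariance, principal components, dynamic
    cross-correlation, free-energy landscapes over principal-component
    projections), grid-based binding-pocket volume with inclusion/exclusion
    spheres, and single-trajectory MM-GB(SA) binding free energies with
    per-residue decomposition and computational alanine scanning. Includes
    seeded synthetic-ensemble generators with known ground truth for
    validation, and a config-driven pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
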