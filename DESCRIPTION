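Package: asmdipole
Title: Electrostatic and Hydrophobic Dipole Energetics of Protein Self-Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained analysis of protein self-assembly driven by
    electrostatic and hydrophobic pseudo dipole moments. Computes per-monomer
    dipole vectors from 3D structures (PDB/mmCIF), evaluates pairwise
    dipole-dipole interaction pseudo-energies, builds cumulative
    assembly-energy growth curves, scans rotations and translations of a
    monomer around the native dimer geometry, and classifies an assembly as
    electrostatically or hydrophobically driven. Includes a synthetic-fixture
    generator (toy monomers and helical assemblies with closed-form energies)
    so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
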