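Package: symrmsd
Title: Symmetry-Corrected RMSD Calculations for Molecular Conformers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Root mean square displacement (RMSD) calculations between
    conformers of the same molecule, as used to score docking poses against a
    crystallographic reference. Implements the standard positional RMSD, the
    rotation-minimised RMSD via the quaternion characteristic polynomial (QCP)
    method, a per-element Hungarian (linear sum assignment) RMSD, and the
    symmetry-corrected RMSD obtained by minimising over all graph isomorphisms
    of the molecular graph (with optional QCP minimisation and isomorphism
    caching). The core API is toolkit-agnostic: it consumes plain coordinate
    matrices, atomic numbers and adjacency matrices. A reader layer turns
    SDF, MOL2 and PDB files into these structures, and a command-line tool
    exposes standard and symmetry-corrected RMSD over structure files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    igraph,
    ChemmineR,
    bio3d,
    ChemmineOB,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
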