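Package: pepforge
Title: Build, Sample and Regularize Capped Peptide Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Generates capped peptide fragments of arbitrary sequence from
    idealized internal-coordinate residue templates, with exact control of
    backbone (phi, psi, omega) and side-chain (chi) torsion angles.
    Conformations can be sampled from continuous von Mises mixture models
    over the Ramachandran plot and side-chain rotamer distributions, steric
    clashes are removed by a dihedral-restrained conjugate-gradient
    regularization procedure, and structures are written as PDB or XYZ files
    or as input decks for quantum chemistry programs (Gaussian-style .com,
    GAMESS-style .inp).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    optparse,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
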