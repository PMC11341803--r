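Package: molcond
Title: Molecular Conductance from the Liouville Quantum Master Equation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the linear-response electronic conductance of molecules
    from a single-electron Hamiltonian and overlap matrix (e.g. exported from
    an extended-Hueckel code). Implements the full Liouville-master-equation
    conductance via the linearized evolution superoperator, its decomposition
    into coherent tunneling (Landauer-Buettiker), thermal-excitation and mixed
    mechanisms, spatially continuous conductivity maps on 3-D grids with
    Gaussian cube and OpenDX output, a time-domain master-equation oracle for
    validation, and generators for synthetic tight-binding and donor-bridge-
    acceptor model molecules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
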