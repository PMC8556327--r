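Package: oligoring
Title: Geometry, Energetics and Sedimentation Analysis of Ring-Shaped
    Protein Oligomers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing cyclic (Cn) and dihedral (Dn) protein
    ring assemblies such as phycobiliprotein hexamers and octamers: reading
    and writing macromolecular coordinate files, Kabsch rigid-body
    superposition, ring symmetry detection, inter-protomer rotation angles
    and anchor-residue angle measurements, chromophore (phycocyanobilin)
    distance networks, Shrake-Rupley solvent-accessible surface areas with
    interface burial and contact statistics, an oligomer assembly free-energy
    pathway model, and analytical ultracentrifugation analysis: a
    mass-conserving Lamm-equation solver, continuous c(s) distribution
    fitting by regularized non-negative least squares, s20,w standardization
    and Svedberg molecular-weight estimation. Includes generators for
    synthetic ring assemblies and sedimentation-velocity experiments with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    Biostrings,
    graphics,
    grDevices,
    jsonlite,
    pracma,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
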