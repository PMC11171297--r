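Package: paircc
Title: Pair Coupled-Cluster Doubles with Linearized Corrections and Response Dipole Moments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Electronic-structure toolkit for seniority-zero coupled-cluster
    methods. Implements pair coupled-cluster doubles (pCCD) with and without
    variational orbital optimization, a posteriori linearized coupled-cluster
    corrections (LCCD, LCCSD) on the pCCD reference, the Lambda equations and
    response one-particle density matrices of all of these, and electric
    dipole moments and dipole-moment surfaces computed from those densities.
    Includes a compact Gaussian atomic-orbital integral engine
    (McMurchie-Davidson), restricted Hartree-Fock with DIIS, Pipek-Mezey
    localization, Cholesky decomposition of two-electron integrals, FCIDUMP
    input/output, and brute-force determinant-space oracles (full and
    seniority-restricted configuration interaction) used to verify every
    solver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
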