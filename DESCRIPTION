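Package: sapt1dm
Title: First-Order Symmetry-Adapted Perturbation Theory with Double Exchange
    from Monomer Density Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the first-order interaction energy of weakly bound
    dimers in symmetrized Rayleigh-Schrodinger perturbation theory from
    reduced density matrices of the monomers: the electrostatic energy and
    the exchange energy through single (S^2) and double (S^4) intermolecular
    overlap expansion orders, with a general-order overlap-expansion
    assembler.  Monomer states may be Hartree-Fock determinants, full CI or
    CAS(2,n)SCF wave functions, or strongly orthogonal geminal (APSG/GVB-PP)
    products, including an approximate CAS(n,n)-to-GVB-PP mapping.  Includes
    a self-contained Gaussian integral engine (McMurchie-Davidson) operating
    in the dimer-centered basis, a factorized geminal fast path for the
    double-exchange terms, and an exact determinant-space oracle for
    validation on small systems.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
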