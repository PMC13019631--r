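Package: f12quad
Title: Seminumerical Exchange-Type Intermediates for Explicitly Correlated
    MP2-F12 Calculations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Evaluates the exchange-type V, X and B intermediates of the
    closed-shell MP2-F12(3C/FIX) correction with a hybrid scheme that
    combines numerical quadrature (NQ), density fitting (DF) and the
    complementary-auxiliary-basis-set resolution of the identity (CABS-RI),
    reducing the formal scaling of the products of four-center two-electron
    integrals from fifth to fourth order in system size.  Ships its own
    Gaussian integral engine (McMurchie-Davidson recursions with a
    Slater-type-geminal Gaussian expansion of the correlation factor), a
    minimal restricted Hartree-Fock reference, Becke-partitioned pruned
    molecular grids, and a dense brute-force oracle so that every
    reformulated contraction can be validated on small closed-shell systems.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
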