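Package: thcmp2
Title: Hyperfine Coupling Constants from Tensor-Hypercontracted Laplace AO-MP2
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes isotropic hyperfine coupling constants (Fermi-contact
    couplings) of open-shell molecules at the unrestricted MP2 level via the
    analytic first derivative of the Laplace-transformed atomic-orbital MP2
    energy with respect to the nuclear magnetic moment.  Electron-repulsion
    integral contractions are performed in tensor-hypercontracted (THC) form
    with Cholesky-decomposed pseudodensities, density fitting in an attenuated
    Coulomb metric, and natural-blocking sparsity screening of the
    exchange-like terms.  Includes a self-contained Gaussian-integral and
    unrestricted Hartree-Fock engine, dense brute-force oracles, and a
    finite-difference derivative oracle for validation on small radicals.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
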