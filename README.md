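# thcmp2 — isotropic hyperfine couplings from tensor-hypercontracted Laplace AO-MP2

`thcmp2` computes **isotropic hyperfine coupling constants** (HFCCs, the
Fermi-contact couplings measured in EPR spectroscopy, in MHz) of open-shell
molecules at the unrestricted MP2 level, as the **analytic first derivative
of the Laplace-transformed AO-MP2 energy with respect to the nuclear
magnetic moment**.  It is aimed at method developers who need a compact,
fully testable reference implementation of this derivative machinery:

* Laplace quadrature of the orbital-energy denominator
  (1/x ≈ Σ_κ ω_κ e^(−τ_κ x)) and Cholesky-decomposed pseudodensities
  (CDD);
* the perturbation-independent **R-matrix** intermediates, both as dense
  brute-force oracles and through the **tensor-hypercontraction** (THC)
  factorization (μν|λσ) ≈ Σ_PQ X_μP X_νP Z_PQ X_λQ X_σQ with a
  least-squares kernel fit, density fitting in an attenuated (erfc)
  Coulomb metric, and a Λ-factorized Coulomb precontraction;
* **natural-blocking** sparsity screening of the exchange-like
  contractions via significance lists built from the collocation matrices;
* the response machinery: exponential coupling integrals
  Y(A,B) = ∫₀¹ e^(uA) B e^((1−u)A) du, a Fock-like intermediate, one
  unrestricted **Z-vector (CPSCF)** solve, and the relaxed spin density
  traced with the rank-one Fermi-contact operator;
* a self-contained Gaussian-integral (McMurchie–Davidson, general angular
  momentum, plain and erf/erfc-attenuated kernels) and UHF-SCF engine, so
  the package has no external quantum-chemistry dependency;
* an independent **central-finite-difference oracle** that anchors
  end-to-end derivative correctness to ~10⁻⁶ MHz on the built-in radical
  fixtures.

The total coupling is reported as `A_iso_SCF + A_iso_MP2`, with the SCF
part from the Hellmann–Feynman spin density and the MP2 part from the
relaxed density.

## Worked example

```r
library(thcmp2)

mol <- fixtures()$CH3$molecule     # planar methyl radical, C-H 1.079 A
run <- run_hfcc(mol, run_config()) # THC pipeline, default settings
print(run)
#> Isotropic hyperfine coupling constants (MHz)
#>  nucleus element isotope A_iso_SCF A_iso_MP2 A_iso_total
#>        1       C     13C  278.8214  -37.8914    240.9301
#>        2       H      1H -152.1344   25.7813   -126.3531
#>        3       H      1H -152.1344   25.7952   -126.3392
#>        4       H      1H -152.1344   25.7951   -126.3393

fd <- fd_hfcc_oracle(mol, 1, 1e-5, run_config(), quad = run$quad)
fd$A_total
#> [1] 240.8747
```

Reading the numbers: the UHF spin density puts +278.8 MHz on ¹³C; the MP2
relaxed density corrects it by −37.9 MHz to 240.9 MHz, and the three
protons carry the negative coupling (−126.4 MHz) characteristic of spin
polarization in a planar π radical.  The finite-difference total for the
carbon (240.87 MHz) differs from the THC value only by the THC fit error
(~0.05 MHz); rerun with `run_config(method = "dense")` and the two agree
to ~10⁻⁶ MHz.  (Minimal-basis values are for machinery validation, not for
comparison with experiment.)

A command-line driver is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "hfcc", package="thcmp2"))') \
    run methyl.xyz --multiplicity 2 --basis sto-3g --laplace 7 \
    --omega 0.1 --grid-ratio 3.0 --out results.csv
```

`hfcc validate CH3` runs the oracle battery (dense vs canonical MP2,
analytic vs finite difference, THC vs dense) on a built-in fixture.

## Layout

| Path | Contents |
|---|---|
| `R/engine.R`, `R/scf.R`, `src/integrals.cpp` | integral/SCF engine and adapter layer |
| `R/laplace.R` | quadrature fit, pseudodensities, pivoted Cholesky / CDD |
| `R/thc.R`, `R/thc_contractions.R` | grid, kernel fit, Λ factorization, THC R-matrix algorithms |
| `R/nblock.R` | significance lists and screening screens |
| `R/contractions.R` | dense Laplace-MP2 energy and R-matrix oracles |
| `R/response.R` | Y integrals, Fock-like build, Z-vector CPSCF, HFCC trace |
| `R/driver.R`, `R/fixtures.R`, `inst/cli/hfcc` | end-to-end pipeline, fixtures, CLI |
| `vignettes/thc-mp2-hfcc-methods.Rmd` | methods and design notes |
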