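---
title: "Isotropic hyperfine couplings from tensor-hypercontracted Laplace AO-MP2: models, algorithms, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isotropic hyperfine couplings from tensor-hypercontracted Laplace AO-MP2}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The property and the model

The isotropic hyperfine coupling constant (HFCC) of a nucleus $k$ measures
the Fermi-contact interaction between the electron spin density and the
nuclear magnetic moment:

$$A_{\mathrm{iso}}(k) \;=\; \frac{2}{3}\,\mu_0\, g_e \mu_B\, g_k \mu_N\,
  \rho^{\alpha-\beta}(\mathbf R_k) ,$$

with $\rho^{\alpha-\beta}(\mathbf R_k)$ the spin density at the nuclear
position.  In a Gaussian AO basis the Fermi-contact operator is the rank-one
matrix $H^{FC}_{\mu\nu} = \chi_\mu(\mathbf R_k)\chi_\nu(\mathbf R_k)$
(point-nucleus model; no finite-nucleus correction).  The package evaluates
$A_{\mathrm{iso}}$ at two levels: the unrestricted SCF spin density
(Hellmann–Feynman term) and the correlation correction from the analytic
first derivative of the Laplace-transformed AO-MP2 energy with respect to
the nuclear magnetic moment.  Because the basis functions do not depend on
this perturbation, no integral derivatives arise; the entire correlation
contribution is carried by an effective (relaxed) one-particle density
$D^\eta$ per spin, and
$A^{\mathrm{MP2}}_{\mathrm{iso}} \propto
\mathrm{Tr}\!\left[H^{FC}(D^\alpha - D^\beta)\right]$.

Conversion to MHz uses CODATA 2018 constants and a built-in table of
nuclear g-factors (¹H, ¹¹B, ¹³C, ¹⁴N, ¹⁷O, ¹⁹F, ³¹P).  The prefactor is
about $800.4\,\mathrm{MHz}\cdot g_k$ per atomic unit of spin density; for
the hydrogen atom with its exact density this reproduces the famous
1.42 GHz line.

## Laplace AO-MP2 and the R-matrix intermediates

The orbital-energy denominator is removed with an exponential quadrature
$1/x \approx \sum_\kappa \omega_\kappa e^{-x\tau_\kappa}$ fitted on
$[2\Delta_{\min},\, 2\Delta_{\max}]$ (twice the smallest/largest
occupied–virtual gap per spin, merged over spins, padded by 0.5% so that
finite-difference displacements stay inside).  The fit minimizes the
relative error on a log-spaced sample by Levenberg–Marquardt on log
parameters, warm-started along increasing point counts with a
best-of-candidates selection; the measured maximum relative error is
therefore non-increasing in the point count, and is stored with the
quadrature and propagated into the energy-consistency tests rather than
assumed.  Seven points are the default.

Each quadrature point carries occupied/virtual pseudodensities
$\underline P = C_o e^{+\varepsilon_o \tau_\kappa} C_o^T$,
$\overline P = C_v e^{-\varepsilon_v \tau_\kappa} C_v^T$.  Quadrature
weights are *not* folded into the matrices (either placement is common);
contractions apply $\omega_\kappa$ explicitly, which keeps the weights
testable (energy must be exactly linear in them).

The correlation energy per point is a quartic form in the pseudodensities
with a Coulomb-like and a same-spin exchange-like contraction of the ERI
tensor.  Differentiating with respect to the pseudodensities defines the
R-matrix intermediates: `Rocc` (conjugate to the occupied pseudodensity)
and `Rvirt` (virtual), each split into Coulomb and exchange parts with
`R = RC - RX`.  The dense oracle (`r_dense_oracle`) evaluates these by
literal tensor contraction; the degree-4 Euler identity
$E(\kappa) = \tfrac14\sum_\eta(\mathrm{Tr}[\underline P \overline R] +
\mathrm{Tr}[\overline P \underline R])$ and a directional-derivative test
against numerical differentiation of the point energy pin the definition.

## From R to the derivative: Y integrals and the Z-vector

With $A_{occ} = \tau_\kappa P_{occ}F$ the occupied pseudodensity is
$\underline P(\kappa) = e^{A_{occ}}P_{occ}$ (analogously
$\overline P = e^{-\tau_\kappa P_{virt}F} P_{virt}$), so the derivative of
the correlation energy against a one-electron perturbation reduces to
coupling integrals of the form

$$Y(A,B) = \int_0^1 e^{uA}\, B\, e^{(1-u)A}\, du,$$

the directional-derivative block of the augmented exponential
$\exp\big[\begin{smallmatrix}A & B\\ 0 & A\end{smallmatrix}\big]$.
`solve_Y` evaluates it by a doubling recursion (scaled augmented Taylor
series, then $Y_{2t} = E_t Y_t + Y_t E_t$, $E_{2t}=E_t^2$); the residual of
the commutation identity $AY - YA = e^A B - B e^A$ is checked (contract:
below $10^{-10}$), and an eigenbasis divided-difference solve serves as the
independent oracle in the tests.  With $Y$ from
$(A = \tau P_{occ}F,\ B = P_{occ}\overline R)$ and
$(A = -\tau P_{virt}F,\ B = P_{virt}\underline R)$, all Laplace points
accumulate into

* an explicit relaxed-density part $W^\eta$ (conjugate to $dh^\eta$), and
* the conjugate of the occupied-density response, completed by the
  Fock-like build $\mathcal F^\eta[W] = J[W^\alpha] + J[W^\beta] -
  K[W^\eta]$, which forms the Z-vector right-hand side.

The remaining response term is converted to $\mathrm{Tr}[dh\,D_Z]$ by one
unrestricted Z-vector (CPSCF) solve in the canonical occupied–virtual
space.  The orbital Hessian is symmetric positive definite at a stable SCF;
it is solved directly (pseudo-inverse) for small dimensions and by
conjugate gradients above 800 unknowns.  The pseudo-inverse matters for
radicals with exactly degenerate partially-occupied orbitals (the hydroxyl
$\pi$ SOMO): rotations among degenerate partners are zero modes that a
compatible right-hand side does not touch; the solution is verified by
re-applying the operator (residual below `cpscf_conv`, default $10^{-4}$;
the validation tests use $10^{-9}$ so that finite-difference comparisons at
the $10^{-3}$ MHz level are meaningful).

The derivative enters with opposite signs for the two spin channels
($+\lambda H^{FC}$ for $\alpha$, $-\lambda$ for $\beta$), coupling the
perturbation to the spin density.  The finite-difference oracle
(`fd_hfcc_oracle`) applies exactly this perturbation to the core
Hamiltonian, re-solves the SCF tightly ($10^{-12}$ energy), evaluates the
dense Laplace-MP2 energy **with the frozen unperturbed quadrature**, and
forms the central difference; freezing the quadrature is essential, since
the analytic derivative differentiates the fixed-quadrature energy
functional.  On the fixture radicals the agreement is at the
$10^{-6}$ MHz level, far inside the $10^{-3}$ MHz acceptance band.

## THC factorization

ERIs are factorized in the AO basis as
$(\mu\nu|\lambda\sigma) \approx \sum_{PQ} X_{\mu P}X_{\nu P} Z_{PQ}
X_{\lambda Q}X_{\sigma Q}$ with $X$ the basis values on a real-space grid
and $Z$ from the least-squares normal equations $Z = S^+ W S^+$,
$S = (X^TX)\circ(X^TX)$.  Numerical choices:

* **Grid.**  Points are selected from an atom-centred parent quadrature
  (Handy radial map, 12 shells/atom by default; 26-point Lebedev angular
  set) by pivoted Cholesky of $S$, stopping at
  $N_{grid} = 3N_{aux}$ (the default ratio).  When the Gram rank is
  exhausted first (common at fixture scale, where the full AO pair space is
  spanned), the selection is padded with the remaining highest-weight
  parent points — an over-complete grid markedly improves the conditioning
  of the fit.  Points whose basis products underflow are excluded from the
  fit.
* **Conditioning.**  $S$ is Jacobi-preconditioned (grid products normalized
  to unit diagonal) before the relative eigenvalue cutoff ($10^{-10}$) of
  the pseudo-inverse; the condition number is logged and guarded.
* **W projection.**  Through density-fitting factors by default;
  `eri_source = "dense"` gives the exact projection used by the saturated-
  grid oracle tests.  A Schwarz screen (relative $10^{-12}$) drops
  negligible AO pairs.
* **Metric.**  The density fitting uses the attenuated Coulomb metric: fit
  coefficients determined with the short-range kernel
  $\mathrm{erfc}(\omega r)/r$ (default $\omega = 0.1$, i.e. nearly the
  Coulomb metric with a $\sim 10$ bohr localization range), recombined with
  the full Coulomb two-centre matrix.  $\omega \to 0$ recovers the Coulomb
  metric; large $\omega$ trades accuracy for locality, and the tests assert
  this quality ordering rather than assuming it.
* **Auxiliary basis.**  Even-tempered, generated per atom from the orbital
  basis (ratio $\beta = 2.3$; angular momenta to $l_{\max}+1$; exponent
  ranges from primitive pair sums that can couple to the target $l$).
* **Kernel factorization.**  $Z = \Lambda\Lambda^T$ by symmetric
  eigendecomposition; eigenvalues below $10^{-12}\lambda_{\max}$ (including
  all negatives beyond noise) are clamped, counted, and reported, and the
  unclamped $Z$ is retained so that the $\Lambda$ path can be A/B-tested.

## THC contractions and natural blocking

The Coulomb-like R parts need one precontraction
$D = Z(A\circ B)Z$ per point and spin ($A = \underline X^T \underline X$,
$B = \overline X^T\overline X$ are the grid-basis pseudodensities, built
from collocations transformed with the pivoted-Cholesky pseudo-MO factors),
then only a Schur product and two matrix multiplies; occupied and virtual
variants interchange $A$ and $B$.  Opposite-spin correlation enters only
here.

The exchange-like parts batch over the occupied pseudo-orbital index $j$
with $w_Q = \underline X_{jQ}$: the shared intermediate
$C_1 = Z\,\mathrm{diag}(w)\,B$ is computed once per $j$ and accumulated as
$E \mathrel{+}= C_1 \circ C_1^T$ (occupied part) and
$F \mathrel{+}= (A \circ C_1)\,Z\,\mathrm{diag}(w)$ (virtual part), so no
three-index tensor is ever materialized.  Natural blocking restricts the
grid indices through significance lists: $\{P_j\}$ from the occupied
collocation screen $|\underline X_{jP}| > \varepsilon_{Sj}$, and
$\{R_j\}$ by composing the grid–virtual list
($|\overline X_{bR}| > \varepsilon_{bR}$) with the orbital–orbital list
($\max_P |\underline X_{jP}\overline X_{bP}| > \varepsilon_{bj}$) over the
shared virtual index.  Membership uses a strict inequality, and lists are
sorted ascending, so screened contractions are deterministic; zero
thresholds reproduce the unscreened result bit-for-bit.  The defaults
$\varepsilon_{Sj}=10^{-3}$, $\varepsilon_{bR}=\varepsilon_{bj}=10^{-2}$
shift the fixture couplings by well under 0.1 MHz (measured in the
acceptance battery); at fixture scale the lists stay dense, so these runs
exercise correctness of the screening machinery, not its asymptotic
speedup.

## Fixtures: what they emulate and what they do not

The built-in set (H, OH, CH₃, NH₂, H₂O, H₂, n-propyl) spans one-electron
exactness, degenerate SOMOs, planar π radicals, closed-shell controls, and
the shortest member of the linear alkyl-radical series.  Geometries are
standard experimental/idealized values.  The shipped bases are a minimal
set (three-Gaussian Slater fits with standard zeta scaling) and a
split-valence "dz" variant.  Passing the battery demonstrates the internal
consistency of the derivative machinery — it does not demonstrate basis-set
convergence of the couplings themselves (minimal-basis spin densities at
nuclei are qualitative at best), nor production-scale screening behaviour,
nor agreement with experimental HFCCs, all of which require larger bases,
EPR-tuned contraction schemes, and molecule sizes beyond desk scale.

## Known limitations

* AO-basis THC with generated (parent + pivoted-Cholesky) grids degrades
  for the split-valence basis: core-product directions of the pair space
  are poorly represented, and the pseudodensity contractions amplify the
  fit error by roughly $\|\overline P\|^3 N^3$.  In the minimal basis the
  standard pipeline reproduces dense R-matrices to a few $10^{-5}$
  (saturated grids: $10^{-9}$); in the dz basis expect $10^{-3}$-level
  R-errors and sub-MHz (not sub-0.1-MHz) coupling shifts.  Grids
  hand-optimized per basis would remove this gap.
* Only the isotropic (Fermi-contact) coupling is computed: no dipolar
  (anisotropic) tensor, no spin–orbit contributions, no geometric
  gradients.
* The dense-ERI engine guards at 48 basis functions by design; the THC
  path shares the SCF Fock builds with it, so the package as a whole is a
  validation-scale implementation.
* UHF references can be spin-contaminated; the MP2 correction inherits
  that sensitivity.

## Problem sizes used in the shipped validation

The test battery and the acceptance script run minimal-basis fixtures
(1–22 basis functions, THC grids up to ~1000 points, 4–7 Laplace points),
chosen so the whole suite exercises every code path — dense oracles, RI,
THC, screening, response, finite differences — in about two minutes on one
CPU.
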