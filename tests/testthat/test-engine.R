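# Engine adapter: SCF contexts, Fermi-contact integrals, dense ERIs,
# density-fitting factors, collocation.

test_that("converged contexts satisfy the density-matrix identities", {
  for (nm in c("H", "OH", "H2O", "CH3")) {
    ctx <- cached_ctx(nm)
    for (sp in c("alpha", "beta")) {
      P <- ctx$P_occ[[sp]]
      # S-metric idempotency
      expect_lt(max(abs(P %*% ctx$S %*% P - P)), 1e-8)
      # Pocc + Pvirt equals the overlap inverse
      expect_lt(max(abs(P + ctx$P_virt[[sp]] - ctx$S_inv)), 1e-8)
      # converged Fock commutator
      Fm <- ctx$F[[sp]]
      expect_lt(max(abs(Fm %*% P %*% ctx$S - ctx$S %*% P %*% Fm)), 1e-6)
    }
  }
})

test_that("closed shells treated unrestricted are exactly spin symmetric", {
  ctx <- cached_ctx("H2O")
  expect_equal(ctx$P_occ$alpha, ctx$P_occ$beta, tolerance = 1e-12)
  expect_equal(ctx$eps$alpha, ctx$eps$beta, tolerance = 1e-10)
})

test_that("one-electron system: SCF equals the core-Hamiltonian bound state", {
  ctx <- cached_ctx("H")
  expect_identical(ctx$n_occ$alpha, 1L)
  expect_identical(ctx$n_occ$beta, 0L)
  # independent oracle: lowest generalized eigenvalue of (h, S)
  X <- thcmp2:::sym_inv_sqrt(ctx$S)
  e_min <- min(eigen(t(X) %*% ctx$h %*% X, symmetric = TRUE)$values)
  expect_equal(ctx$E_SCF, e_min, tolerance = 1e-10)
  expect_identical(mp2_energy_laplace_dense(ctx, laplace_for_scf(ctx)), 0)
})

test_that("Fermi-contact operator is a rank-one outer product", {
  ctx <- cached_ctx("CH3")
  for (k in c(1L, 2L)) {
    fc <- fermi_contact_integrals(ctx, k)
    expect_equal(fc$H_FC, t(fc$H_FC))
    sv <- svd(fc$H_FC)$d
    expect_equal(sum(sv > 1e-12 * sv[1]), 1L)  # rank exactly 1
    # bilinear consistency: Tr(H_FC D) equals the pointwise density
    D <- ctx$P_occ$alpha
    expect_equal(sum(fc$H_FC * D), as.numeric(fc$chi %*% D %*% fc$chi),
                 tolerance = 1e-10)
  }
  expect_error(fermi_contact_integrals(ctx, 99L))
})

test_that("Fermi-contact value matches the analytic Gaussian at its centre", {
  ctx <- cached_ctx("H")
  fc <- fermi_contact_integrals(ctx, 1L)
  # contracted STO-3G 1s of hydrogen evaluated at r = 0, by direct formula
  sh <- ctx$shells[[1]]
  nrm <- (2 * sh$exps / pi)^0.75
  raw <- sum(sh$coefs * nrm)
  sself <- sum(outer(sh$coefs * nrm, sh$coefs * nrm) *
                 (pi / outer(sh$exps, sh$exps, "+"))^1.5)
  val <- raw / sqrt(sself)
  expect_equal(fc$H_FC[1, 1], val^2, tolerance = 1e-12)
})

test_that("a nucleus far from all basis centres yields a vanishing operator", {
  mol <- molecule(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 60)), 1L, 2L)
  ctx <- build_scf_context(mol)
  fc <- fermi_contact_integrals(ctx, 2L)
  # basis function on atom 1 evaluated 60 A away
  expect_lt(abs(fc$H_FC[1, 1]), 1e-30)
})

test_that("dense ERI tensor has the 8-fold permutational symmetry", {
  eri <- ao_eri_dense(cached_ctx("OH"))
  expect_gt(eri[1, 1, 1, 1], 0)
  expect_equal(eri, aperm(eri, c(2, 1, 3, 4)), tolerance = 1e-12)
  expect_equal(eri, aperm(eri, c(3, 4, 1, 2)), tolerance = 1e-12)
  expect_equal(eri, aperm(eri, c(2, 1, 4, 3)), tolerance = 1e-12)
})

test_that("dense ERI size guard is deterministic", {
  expect_error(build_scf_context(fixtures()$H2O$molecule, eri_guard = 3L),
               "guard")
})

test_that("RI factors reconstruct ERIs within the fitting envelope", {
  ctx <- cached_ctx("H2")
  ri <- ri_factors(ctx, "coulomb")
  err <- max(abs(thcmp2:::ri_reconstruct_eri(ri) - ao_eri_dense(ctx)))
  expect_lt(err, 1e-4)
  # attenuated metric at the default strength is as good; strong
  # attenuation (local metric limit) must not improve on it
  ctx2 <- cached_ctx("H2O")
  eri0 <- ao_eri_dense(ctx2)
  e01 <- max(abs(thcmp2:::ri_reconstruct_eri(
    ri_factors(ctx2, "attenuated", omega = 0.1)) - eri0))
  e50 <- max(abs(thcmp2:::ri_reconstruct_eri(
    ri_factors(ctx2, "attenuated", omega = 50)) - eri0))
  expect_lt(e01, 1e-3)
  expect_gte(e50, e01)
  expect_identical(ri_factors(ctx, "attenuated")$omega, 0.1)  # default
})

test_that("collocation columns behave like basis-function values", {
  ctx <- cached_ctx("CH3")
  pts <- rbind(c(0.1, 0.2, 0.3), c(1e6, 0, 0), c(0.1, 0.2, 0.3))
  X <- collocate(ctx, pts)
  expect_equal(X[, 1], X[, 3])            # duplicated point
  expect_true(all(abs(X[, 2]) < 1e-300))  # effectively at infinity
  # consistency with the Fermi-contact vector at a nuclear position
  fc <- fermi_contact_integrals(ctx, 2L)
  xyz <- ctx$mol$coords * 1.8897259886
  expect_equal(as.numeric(collocate(ctx, xyz[2, , drop = FALSE])), fc$chi)
})
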