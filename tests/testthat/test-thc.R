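# THC grid construction, kernel fit, factorization, reconstruction.

test_that("grid selection returns distinct, atom-sorted points", {
  ctx <- cached_ctx("H2O")
  g <- build_thc_grid(ctx, target_ratio = 1)
  expect_identical(nrow(g$points), g$n_grid)
  d <- as.matrix(dist(g$points))
  diag(d) <- 1
  expect_gt(min(d), 1e-8)
  expect_true(all(diff(g$atom) >= 0))  # atom-blocked ordering
  # requesting more than the parent provides is an error
  expect_error(build_thc_grid(ctx, target_n = 1e7), "parent")
})

test_that("whole-parent selection returns the full parent grid", {
  ctx <- cached_ctx("H2")
  pg <- thcmp2:::parent_grid(ctx$mol, 6L)
  g <- build_thc_grid(ctx, target_n = nrow(pg$points), n_rad = 6L)
  expect_identical(g$n_grid, nrow(pg$points))
})

test_that("ERI reconstruction error decreases with grid size", {
  ctx <- cached_ctx("H2")
  eri0 <- ao_eri_dense(ctx)
  meds <- vapply(c(0.5, 1, 3), function(r) {
    thc <- build_thc(ctx, target_ratio = r, eri_source = "dense")
    median(abs(thcmp2:::thc_eri_tensor(thc) - eri0))
  }, 0)
  # non-increasing up to 10% slack (non-variational fit) and machine noise
  expect_true(all(meds[-1] <= 1.1 * meds[-3] + 1e-12))
})

test_that("THC-MP2 energy error decreases from 1x to 3x grids", {
  for (nm in c("H2", "H2O")) {
    ctx <- cached_ctx(nm)
    q <- cached_quad(nm, 5L)
    e_ref <- mp2_energy_laplace_dense(ctx, q)
    errs <- vapply(c(1, 3), function(r) {
      thc <- build_thc(ctx, target_ratio = r, eri_source = "dense")
      abs(thc_mp2_energy(ctx, thc, q) - e_ref)
    }, 0)
    expect_lt(errs[2], errs[1])
  }
})

test_that("fitted kernel is symmetric and reproducible bit-for-bit", {
  ctx <- cached_ctx("H2O")
  thc <- build_thc(ctx)
  expect_equal(thc$Z, t(thc$Z), tolerance = 1e-10)
  ri <- ri_factors(ctx)
  Z1 <- fit_Z(thc$X, ri = ri)$Z
  Z2 <- fit_Z(thc$X, ri = ri)$Z
  expect_identical(Z1, Z2)
  expect_identical(thc$metric$metric, "attenuated")
  expect_identical(thc$metric$omega, 0.1)
})

test_that("saturated-grid exact-projection fit reproduces the dense ERIs", {
  ctx <- cached_ctx("H2")
  thc <- build_thc(ctx, eri_source = "dense",
                   grid = build_thc_grid(ctx, target_n = 200))
  expect_lt(max(abs(thcmp2:::thc_eri_tensor(thc) - ao_eri_dense(ctx))), 1e-4)
})

test_that("kernel factorization clamps and reports negative directions", {
  f <- factorize_Z(diag(4))
  expect_equal(tcrossprod(f$Lambda), diag(4), tolerance = 1e-12)
  expect_identical(f$clamp_report$n_discarded, 0L)
  # constructed indefinite kernel: the negative direction is discarded
  Q <- qr.Q(qr(matrix(rnorm(16), 4)))
  Z <- Q %*% diag(c(2, 1, 0.5, -1e-6 * 2)) %*% t(Q)
  f2 <- factorize_Z(Z)
  expect_identical(f2$clamp_report$n_discarded, 1L)
  expect_lt(f2$clamp_report$most_negative, 0)
  expect_lte(max(abs(tcrossprod(f2$Lambda) - Z)),
             abs(f2$clamp_report$most_negative) + 1e-12)
  expect_error(factorize_Z(-diag(3)), "clamped")
})

test_that("reconstruction respects the algebraic pair symmetry", {
  ctx <- cached_ctx("H2O")
  thc <- build_thc(ctx)
  set.seed(9)
  idx <- matrix(sample(ctx$n_bf, 40, replace = TRUE), 10)
  v1 <- reconstruct_eri(thc, idx[, 1], idx[, 2], idx[, 3], idx[, 4])
  v2 <- reconstruct_eri(thc, idx[, 2], idx[, 1], idx[, 4], idx[, 3])
  v3 <- reconstruct_eri(thc, idx[, 3], idx[, 4], idx[, 1], idx[, 2])
  expect_identical(v1, v2)
  expect_equal(v1, v3, tolerance = 1e-12)
  thc0 <- thc; thc0$Z <- thc$Z * 0
  expect_identical(reconstruct_eri(thc0, 1, 2, 3, 4), 0)
})

test_that("transformed collocations have the contracted shapes", {
  ctx <- cached_ctx("CH3")
  q <- cached_quad("CH3")
  pd <- build_pseudodensities(ctx, q, 1L)
  cdd <- cholesky_mos(pd)
  thc <- build_thc(ctx, target_ratio = 1)
  col <- build_collocation(thc, cdd)
  expect_identical(nrow(col$Xo$alpha), ncol(cdd$Locc$alpha))
  expect_identical(nrow(col$Xv$beta), ncol(cdd$Lvirt$beta))
  expect_equal(col$X, collocate(ctx, thc$grid$points))
  # empty spin channel: zero rows
  ctxH <- cached_ctx("H")
  pdH <- list(kappa = 1, omega = 1, tau = 1,
              Pocc = list(alpha = ctxH$P_occ$alpha,
                          beta = matrix(0, 1, 1)),
              Pvirt = list(alpha = matrix(0, 1, 1),
                           beta = ctxH$P_virt$beta))
  cddH <- cholesky_mos(pdH)
  colH <- build_collocation(collocate(ctxH, matrix(c(0, 0, 0.3), 1)), cddH)
  expect_identical(nrow(colH$Xo$beta), 0L)
})
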