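# Response machinery: Y integrals, Fock-like builds, Z-vector CPSCF,
# relaxed densities, and the hyperfine trace.

test_that("Y integral: zero input, linearity, and residual contract", {
  set.seed(31)
  A <- matrix(rnorm(36), 6)
  B <- matrix(rnorm(36), 6)
  y0 <- solve_Y(A, matrix(0, 6, 6))
  expect_identical(max(abs(y0$Y)), 0)
  y1 <- solve_Y(A, B)
  y3 <- solve_Y(A, 3 * B)
  expect_equal(y3$Y, 3 * y1$Y, tolerance = 1e-12)
  expect_lt(y1$residual, 1e-10)
})

test_that("Y integral matches the eigenbasis divided-difference solve", {
  # independent oracle: in the eigenbasis of A the defining integral has
  # the closed form Y_pq = B_pq (e^{a_p} - e^{a_q}) / (a_p - a_q)
  set.seed(32)
  for (n in c(2L, 5L)) {
    A <- matrix(rnorm(n * n), n)
    B <- matrix(rnorm(n * n), n)
    ev <- eigen(A)
    V <- ev$vectors; a <- ev$values
    Bt <- solve(V, B %*% V)
    phi <- outer(a, a, function(p, q)
      ifelse(abs(p - q) < 1e-12, exp(p), (exp(p) - exp(q)) / (p - q)))
    Y_ref <- Re(V %*% (Bt * phi) %*% solve(V))
    y <- solve_Y(A, B)
    expect_equal(y$Y, Y_ref, tolerance = 1e-9)
    expect_equal(y$E, Re(V %*% (exp(a) * solve(V))), tolerance = 1e-9)
  }
})

test_that("Fock-like intermediate reproduces the two-electron Fock part", {
  ctx <- cached_ctx("CH3")
  FL <- build_fock_like(ctx$P_occ, ctx)
  for (sp in c("alpha", "beta"))
    expect_lt(max(abs(FL[[sp]] - (ctx$F[[sp]] - ctx$h_spin[[sp]]))), 1e-8)
  # zero density and additivity
  nb <- ctx$n_bf
  zero <- list(alpha = matrix(0, nb, nb), beta = matrix(0, nb, nb))
  expect_identical(max(abs(build_fock_like(zero, ctx)$alpha)), 0)
  set.seed(33)
  D1 <- lapply(zero, function(m) { M <- matrix(rnorm(nb^2), nb); M + t(M) })
  D2 <- lapply(zero, function(m) { M <- matrix(rnorm(nb^2), nb); M + t(M) })
  Dsum <- Map(`+`, D1, D2)
  expect_equal(build_fock_like(Dsum, ctx)$beta,
               build_fock_like(D1, ctx)$beta + build_fock_like(D2, ctx)$beta,
               tolerance = 1e-10)
})

test_that("assembled RHS vanishes for zero R and is spin symmetric", {
  ctx <- cached_ctx("H2O")
  q <- cached_quad("H2O", 4L)
  Rz <- lapply(seq_len(q$K), function(k) {
    nb <- ctx$n_bf
    z <- matrix(0, nb, nb)
    r <- list(Rocc = z, Rvirt = z)
    list(alpha = r, beta = r, kappa = k)
  })
  asm0 <- assemble_rhs(ctx, q, Rz)
  expect_identical(max(abs(asm0$rhs$alpha)), 0)
  expect_identical(max(abs(asm0$W$beta)), 0)
  Rd <- cached_dense_R("H2O", 4L)
  asm <- assemble_rhs(ctx, q, Rd)
  expect_equal(asm$rhs$alpha, asm$rhs$beta, tolerance = 1e-8)
  expect_equal(asm$W$alpha, asm$W$beta, tolerance = 1e-8)
  expect_lt(asm$y_residual, 1e-10)
  # mismatched kappa sets are rejected
  expect_error(assemble_rhs(ctx, q, Rd[1:2]), "points")
})

test_that("CPSCF: zero RHS, re-application residual, adjoint property", {
  ctx <- cached_ctx("CH3")
  nb <- ctx$n_bf
  zero <- list(alpha = matrix(0, nb, nb), beta = matrix(0, nb, nb))
  cp0 <- solve_cpscf(zero, ctx)
  expect_identical(max(abs(cp0$Dz$alpha)), 0)
  set.seed(34)
  rhs <- lapply(zero, function(m) { M <- matrix(rnorm(nb^2), nb); M + t(M) })
  cp <- solve_cpscf(rhs, ctx, conv = 1e-9)
  expect_lt(cp$residual, 1e-9)
  # adjoint check against brute-force first-order response: for a random
  # symmetric dh, Tr[dPocc rhs] must equal Tr[dh Dz]
  dh <- { M <- matrix(rnorm(nb^2), nb); 1e-5 * (M + t(M)) }
  conv <- list(energy = 1e-13, commutator = 1e-11)
  cxp <- build_scf_context(ctx$mol, conv = conv, h_alpha = dh, h_beta = dh)
  cxm <- build_scf_context(ctx$mol, conv = conv, h_alpha = -dh, h_beta = -dh)
  lhs <- sum(vapply(c("alpha", "beta"), function(sp)
    sum((cxp$P_occ[[sp]] - cxm$P_occ[[sp]]) / 2 * rhs[[sp]]), 0))
  rhs_tr <- sum(dh * (cp$Dz$alpha + cp$Dz$beta))
  expect_equal(lhs, rhs_tr, tolerance = 1e-5)  # FD truncation limited
})

test_that("relaxed density is symmetric; one-electron MP2 part vanishes", {
  ctx <- cached_ctx("CH3")
  q <- cached_quad("CH3", 4L)
  rel <- mp2_relaxed_density(ctx, q, cached_dense_R("CH3", 4L),
                             cpscf_conv = 1e-8)
  for (sp in c("alpha", "beta")) {
    expect_equal(rel$total[[sp]], t(rel$total[[sp]]), tolerance = 1e-9)
    expect_equal(rel$total[[sp]],
                 rel$explicit[[sp]] + rel$response[[sp]], tolerance = 1e-14)
  }
  ctxH <- cached_ctx("H")
  relH <- mp2_relaxed_density(ctxH, laplace_for_scf(ctxH), list())
  expect_identical(max(abs(relH$total$alpha)), 0)
})

test_that("hyperfine couplings: closed-shell zeros and the H-atom value", {
  ctx <- cached_ctx("H2O")
  q <- cached_quad("H2O", 4L)
  rel <- mp2_relaxed_density(ctx, q, cached_dense_R("H2O", 4L))
  for (k in 1:3) {
    r <- compute_hfcc(ctx, rel, k)
    expect_lt(abs(r$A_iso_total), 1e-6)
  }
  ctxH <- cached_ctx("H")
  rH <- compute_hfcc(ctxH, NULL, 1L)
  fc <- fermi_contact_integrals(ctxH, 1L)
  rho <- as.numeric(fc$chi %*% (ctxH$P_occ$alpha - ctxH$P_occ$beta) %*% fc$chi)
  expect_equal(rH$A_iso_SCF,
               thcmp2:::.fc_prefactor_mhz * isotope_g_factor("H")$g * rho,
               tolerance = 1e-12)
  expect_identical(rH$A_iso_MP2, 0)
  expect_equal(rH$A_iso_total, rH$A_iso_SCF + rH$A_iso_MP2)
  expect_error(compute_hfcc(ctx, rel, 2L) -> r2, NA)
  # unknown isotope
  mol_he <- molecule("He", matrix(0, 1, 3), 0L, 1L)
  ctx_he <- build_scf_context(mol_he)
  expect_error(compute_hfcc(ctx_he, NULL, 1L), "available")
})

test_that("flipping alpha and beta everywhere negates the coupling", {
  ctx <- cached_ctx("OH")
  q <- cached_quad("OH", 4L)
  Rlist <- cached_dense_R("OH", 4L)
  rel <- mp2_relaxed_density(ctx, q, Rlist, cpscf_conv = 1e-8)
  a0 <- vapply(1:2, function(k) compute_hfcc(ctx, rel, k)$A_iso_total, 0)
  ctx_f <- flip_spins(ctx)
  Rf <- lapply(seq_len(q$K), function(k)
    r_dense_oracle(ctx_f, build_pseudodensities(ctx_f, q, k)))
  rel_f <- mp2_relaxed_density(ctx_f, q, Rf, cpscf_conv = 1e-8)
  af <- vapply(1:2, function(k) compute_hfcc(ctx_f, rel_f, k)$A_iso_total, 0)
  expect_equal(af, -a0, tolerance = 1e-8)
})

test_that("analytic derivative matches finite differences (spot check)", {
  mol <- fixtures()$OH$molecule
  cfg <- run_config(method = "dense", cpscf_conv = 1e-9)
  run <- run_hfcc(mol, cfg)
  fd <- fd_hfcc_oracle(mol, 2L, 1e-5, cfg, quad = run$quad)
  expect_lt(abs(run$results$A_iso_total[2] - fd$A_total), 1e-3)
})
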