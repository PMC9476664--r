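# Dense and THC contraction engines: Laplace-MP2 energies, R-matrix
# oracles, the Coulomb/exchange THC algorithms, and the screened
# exchange-energy contraction.

test_that("Laplace AO-MP2 matches the canonical MO oracle within fit error", {
  for (nm in c("H2", "H2O", "OH")) {
    ctx <- cached_ctx(nm)
    q <- laplace_for_scf(ctx, 8L)
    ecan <- mp2_energy_canonical(ctx)
    elap <- mp2_energy_laplace_dense(ctx, q)
    expect_lt(abs(elap - ecan), q$max_rel_error * abs(ecan) + 1e-12)
  }
})

test_that("Laplace-MP2 energy is linear in the quadrature weights", {
  ctx <- cached_ctx("H2O")
  q <- cached_quad("H2O", 4L)
  e1 <- mp2_energy_laplace_dense(ctx, q)
  q2 <- q; q2$omega <- 2 * q$omega
  expect_equal(mp2_energy_laplace_dense(ctx, q2), 2 * e1, tolerance = 1e-12)
})

test_that("R oracle: zero pseudodensities give zero R", {
  ctx <- cached_ctx("OH")
  pd <- build_pseudodensities(ctx, cached_quad("OH", 4L), 1L)
  for (sp in c("alpha", "beta")) {
    pd$Pocc[[sp]] <- pd$Pocc[[sp]] * 0
    pd$Pvirt[[sp]] <- pd$Pvirt[[sp]] * 0
  }
  R <- r_dense_oracle(ctx, pd)
  expect_identical(max(abs(R$alpha$Rocc)), 0)
  expect_identical(max(abs(R$beta$Rvirt)), 0)
})

test_that("R oracle is spin symmetric for closed shells", {
  ctx <- cached_ctx("H2O")
  pd <- build_pseudodensities(ctx, cached_quad("H2O", 4L), 2L)
  R <- r_dense_oracle(ctx, pd)
  expect_equal(R$alpha$Rocc, R$beta$Rocc, tolerance = 1e-10)
  expect_equal(R$alpha$Rvirt, R$beta$Rvirt, tolerance = 1e-10)
})

test_that("R oracle parts are consistent with the point energy (Euler)", {
  ctx <- cached_ctx("CH3")
  q <- cached_quad("CH3", 5L)
  for (kap in c(1L, 3L)) {
    pd <- build_pseudodensities(ctx, q, kap)
    R <- r_dense_oracle(ctx, pd)
    # direct energy of this single point
    q1 <- q; q1$omega <- q$omega * (seq_len(q$K) == kap)
    e_dir <- mp2_energy_laplace_dense(ctx, q1)
    expect_equal(thcmp2:::laplace_point_energy_from_R(pd, R), e_dir,
                 tolerance = 1e-12)
    # Coulomb/exchange partition: parts sum to the total
    for (sp in c("alpha", "beta")) {
      expect_equal(R[[sp]]$Rocc, R[[sp]]$Rocc_C - R[[sp]]$Rocc_X,
                   tolerance = 1e-14)
      expect_equal(R[[sp]]$Rvirt, R[[sp]]$Rvirt_C - R[[sp]]$Rvirt_X,
                   tolerance = 1e-14)
    }
  }
})

test_that("R oracle linearizes the point energy (directional derivative)", {
  ctx <- cached_ctx("NH2")
  q <- cached_quad("NH2", 4L)
  pd <- build_pseudodensities(ctx, q, 2L)
  R <- r_dense_oracle(ctx, pd)
  point_energy <- function(p) {
    q1 <- q; q1$omega <- q$omega * (seq_len(q$K) == 2L)
    # rebuild through the generic contraction path
    T4 <- ao_eri_dense(ctx); U <- thcmp2:::eri_exchange_view(T4)
    E <- 0
    half <- lapply(c(alpha = "alpha", beta = "beta"), function(sp)
      thcmp2:::contract_mode(
        thcmp2:::contract_mode(T4, p$Pocc[[sp]], 1), p$Pvirt[[sp]], 2))
    for (sp in c("alpha", "beta")) for (sp2 in c("alpha", "beta")) {
      Tt <- thcmp2:::contract_mode(
        thcmp2:::contract_mode(half[[sp]], p$Pocc[[sp2]], 3),
        p$Pvirt[[sp2]], 4)
      E <- E - 0.5 * p$omega * sum(Tt * T4)
      if (sp == sp2) E <- E + 0.5 * p$omega * sum(Tt * U)
    }
    E
  }
  set.seed(21)
  rand_symm <- function(n) { M <- matrix(rnorm(n * n), n); (M + t(M)) / 2 }
  h <- 1e-5
  for (case in list(c("Pocc", "alpha", "Rocc"), c("Pvirt", "beta", "Rvirt"))) {
    D <- rand_symm(ctx$n_bf) * h
    pp <- pd; pp[[case[1]]][[case[2]]] <- pp[[case[1]]][[case[2]]] + D
    pm <- pd; pm[[case[1]]][[case[2]]] <- pm[[case[1]]][[case[2]]] - D
    fd <- (point_energy(pp) - point_energy(pm)) / 2
    an <- sum(D * R[[case[2]]][[case[3]]])
    expect_equal(an, fd, tolerance = 1e-6)
  }
})

test_that("RI-CDD integral route agrees with the dense route", {
  ctx <- cached_ctx("CH3")
  q <- cached_quad("CH3", 4L)
  pd <- build_pseudodensities(ctx, q, 2L)
  Rd <- r_dense_oracle(ctx, pd)
  # second oracle: identical contractions over the RI-reconstructed ERIs
  ctx_ri <- ctx
  ctx_ri$eri_env <- thcmp2:::make_eri_env(
    thcmp2:::ri_reconstruct_eri(ri_factors(ctx, "coulomb")))
  Rri <- r_dense_oracle(ctx_ri, pd)
  expect_lt(max_R_diff(list(Rd), list(Rri)), 1e-4)
})

test_that("grid pseudodensities are PSD Gram matrices with exact traces", {
  ctx <- cached_ctx("CH3")
  pd <- build_pseudodensities(ctx, cached_quad("CH3", 4L), 1L)
  cdd <- cholesky_mos(pd)
  thc <- build_thc(ctx, target_ratio = 1)
  col <- build_collocation(thc, cdd)
  gp <- grid_pseudodensities(col$Xo$alpha, col$Xv$alpha)
  expect_gte(min(eigen(gp$A, symmetric = TRUE, only.values = TRUE)$values),
             -1e-12)
  expect_equal(sum(diag(gp$A)), sum(col$Xo$alpha^2), tolerance = 1e-12)
  # rank bound: one occupied pseudo-orbital gives a rank-1 A
  gp1 <- grid_pseudodensities(col$Xo$alpha[1, , drop = FALSE],
                              col$Xv$alpha)
  expect_identical(qr(gp1$A)$rank, 1L)
})

test_that("Lambda-factorized precontraction equals the plain-Z path", {
  ctx <- cached_ctx("H2O")
  pd <- build_pseudodensities(ctx, cached_quad("H2O", 4L), 1L)
  cdd <- cholesky_mos(pd)
  thc <- build_thc(ctx, target_ratio = 1)
  col <- build_collocation(thc, cdd)
  gp <- grid_pseudodensities(col$Xo$alpha, col$Xv$alpha)
  D1 <- coulomb_precontraction(gp$A, gp$B, thc$Lambda)
  D2 <- coulomb_precontraction(gp$A, gp$B, NULL, Z_direct = thc$Z_psd)
  expect_lt(max(abs(D1 - D2)), 1e-10 * max(1, max(abs(D1))))
  expect_identical(max(abs(coulomb_precontraction(gp$A, gp$B,
                                                  thc$Lambda * 0))), 0)
  # spin symmetry for the closed shell
  gpb <- grid_pseudodensities(col$Xo$beta, col$Xv$beta)
  expect_equal(coulomb_precontraction(gpb$A, gpb$B, thc$Lambda), D1,
               tolerance = 1e-8)
})

test_that("Coulomb R is linear in the precontraction intermediate", {
  ctx <- cached_ctx("H2O")
  pd <- build_pseudodensities(ctx, cached_quad("H2O", 4L), 1L)
  cdd <- cholesky_mos(pd)
  thc <- build_thc(ctx, target_ratio = 1)
  col <- build_collocation(thc, cdd)
  gp <- grid_pseudodensities(col$Xo$alpha, col$Xv$alpha)
  D <- coulomb_precontraction(gp$A, gp$B, thc$Lambda)
  r1 <- coulomb_R(D, col$X, gp$A, gp$B, pd$omega)
  r2 <- coulomb_R(3 * D, col$X, gp$A, gp$B, pd$omega)
  expect_equal(r2$RoccC, 3 * r1$RoccC, tolerance = 1e-12)
  r0 <- coulomb_R(D * 0, col$X, gp$A, gp$B, pd$omega)
  expect_identical(max(abs(r0$RvirtC)), 0)
})

test_that("THC Coulomb and exchange parts match the dense split", {
  ctx <- cached_ctx("CH3")
  q <- cached_quad("CH3", 4L)
  Rd <- lapply(seq_len(q$K), function(k)
    r_dense_oracle(ctx, build_pseudodensities(ctx, q, k)))
  thc <- build_thc(ctx, eri_source = "dense",
                   grid = build_thc_grid(ctx, target_n = 400))
  Rt <- build_R(ctx, thc, q, nb_config(exact = TRUE))
  for (k in c(1L, 3L)) for (sp in c("alpha", "beta")) {
    expect_lt(max(abs(Rt[[k]][[sp]]$Rocc_C - Rd[[k]][[sp]]$Rocc_C)), 1e-8)
    expect_lt(max(abs(Rt[[k]][[sp]]$Rocc_X - Rd[[k]][[sp]]$Rocc_X)), 1e-8)
    expect_lt(max(abs(Rt[[k]][[sp]]$Rvirt_C - Rd[[k]][[sp]]$Rvirt_C)), 1e-8)
    expect_lt(max(abs(Rt[[k]][[sp]]$Rvirt_X - Rd[[k]][[sp]]$Rvirt_X)), 1e-8)
  }
})

test_that("exchange screening at zero thresholds is exact", {
  ctx <- cached_ctx("NH2")
  pd <- build_pseudodensities(ctx, cached_quad("NH2", 4L), 1L)
  cdd <- cholesky_mos(pd)
  thc <- build_thc(ctx, target_ratio = 1)
  col <- build_collocation(thc, cdd)
  ex_exact <- exchange_R(col$Xo$alpha, col$Xv$alpha, thc$Z,
                         nb_config(exact = TRUE), pd$omega, col$X)
  ex_eps0 <- exchange_R(col$Xo$alpha, col$Xv$alpha, thc$Z,
                        nb_config(0, 0, 0), pd$omega, col$X)
  expect_equal(ex_eps0$RoccX, ex_exact$RoccX, tolerance = 1e-14)
  expect_equal(ex_eps0$RvirtX, ex_exact$RvirtX, tolerance = 1e-14)
  # zero virtual channel: no exchange contribution
  ex0 <- exchange_R(col$Xo$alpha, col$Xv$alpha * 0, thc$Z,
                    nb_config(), pd$omega, col$X)
  expect_identical(max(abs(ex0$RoccX)), 0)
})

test_that("full THC R at zero thresholds matches the dense oracle", {
  for (nm in c("CH3", "H2O")) {
    ctx <- cached_ctx(nm)
    q <- cached_quad(nm, 4L)
    Rd <- lapply(seq_len(q$K), function(k)
      r_dense_oracle(ctx, build_pseudodensities(ctx, q, k)))
    thc <- build_thc(ctx)  # default RI pipeline
    Rt <- build_R(ctx, thc, q, nb_config(exact = TRUE))
    expect_lt(max_R_diff(Rt, Rd), 1e-4)
  }
})

test_that("kappa contributions scale independently with their weights", {
  ctx <- cached_ctx("H2O")
  q <- cached_quad("H2O", 4L)
  thc <- build_thc(ctx, target_ratio = 1)
  Rt <- build_R(ctx, thc, q, nb_config(exact = TRUE))
  q2 <- q; q2$omega[2] <- 2 * q$omega[2]
  Rt2 <- lapply(seq_len(q$K), function(k) {
    pd <- build_pseudodensities(ctx, q2, k)
    # same pseudodensities (weights are not folded in), doubled weight
    pd
  })
  Rt2 <- build_R(ctx, thc, q2, nb_config(exact = TRUE))
  expect_equal(Rt2[[2]]$alpha$Rocc, 2 * Rt[[2]]$alpha$Rocc,
               tolerance = 1e-12)
  expect_equal(Rt2[[1]]$alpha$Rocc, Rt[[1]]$alpha$Rocc, tolerance = 1e-12)
})

test_that("screened exchange energy matches the brute-force contraction", {
  ctx <- cached_ctx("H2O")
  pd <- build_pseudodensities(ctx, cached_quad("H2O", 4L), 2L)
  cdd <- cholesky_mos(pd)
  thc <- build_thc(ctx, target_ratio = 1)
  col <- build_collocation(thc, cdd)
  Xo <- col$Xo$alpha; Xv <- col$Xv$alpha; Z <- thc$Z
  e_nb <- exchange_energy_nb(Xo, Xv, Z, nb_config(exact = TRUE))
  # brute force over pseudo-MO quadruples with THC-reconstructed integrals
  no <- nrow(Xo); nv <- nrow(Xv)
  mo_eri <- function(i, a, j, b)
    as.numeric((Xo[i, ] * Xv[a, ]) %*% Z %*% (Xo[j, ] * Xv[b, ]))
  e_ref <- 0
  for (i in 1:no) for (j in 1:no) for (a in 1:nv) for (b in 1:nv)
    e_ref <- e_ref + mo_eri(i, a, j, b) * mo_eri(i, b, j, a)
  expect_equal(e_nb, e_ref, tolerance = 1e-10)
  expect_identical(exchange_energy_nb(Xo, Xv, Z * 0, nb_config()), 0)
})

test_that("exchange-energy screening error shrinks with tighter thresholds", {
  ctx <- cached_ctx("CH3")
  pd <- build_pseudodensities(ctx, cached_quad("CH3", 4L), 1L)
  cdd <- cholesky_mos(pd)
  thc <- build_thc(ctx, target_ratio = 2)
  col <- build_collocation(thc, cdd)
  e0 <- exchange_energy_nb(col$Xo$alpha, col$Xv$alpha, thc$Z,
                           nb_config(exact = TRUE))
  errs <- vapply(c(1e-1, 1e-2, 1e-4), function(e)
    abs(exchange_energy_nb(col$Xo$alpha, col$Xv$alpha, thc$Z,
                           nb_config(e, e, e)) - e0), 0)
  expect_true(all(diff(errs) <= 1e-14))
})
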