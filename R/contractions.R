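# Core MP2 contraction engine.
#
# Dense oracles: the Laplace AO-MP2 energy and the perturbation-independent
# R-matrix intermediates by literal contraction of the AO ERI tensor with
# pseudodensities.  These serve as the reference for the THC fast path.
#
# Conventions: for one Laplace point k with weight w the correlation-energy
# contribution is
#   E(k) = -(w/2) [ sum_{ss'} J^{ss'} - sum_s K^s ],
# where J is the Coulomb-like full contraction of the pseudodensity-
# transformed ERI with the plain ERI, and K the exchange-like one with the
# nu/sigma-crossed ERI.  R-matrices are the derivatives of E(k) with
# respect to the pseudodensities:
#   Rocc = dE/dPocc = -w [ sum_s' DJ^{ss'} - DK^s ]   (traced with dPocc)
#   Rvirt = dE/dPvirt analogously.
# Coulomb and exchange parts are kept separately; total R = RC - RX with
# RC = -w sum DJ and RX = -w DK.

# contract tensor mode `mode` of 4D array T with symmetric matrix M:
# out[.., i', ..] = sum_i M[i, i'] T[.., i, ..]
contract_mode <- function(T4, M, mode) {
  d <- dim(T4)
  perm <- c(mode, setdiff(1:4, mode))
  A <- matrix(aperm(T4, perm), d[mode])
  out <- crossprod(M, A)
  aperm(array(out, d[perm]), order(perm))
}

# exchange-pattern view: U[m,n,l,s] = (m s | l n)
eri_exchange_view <- function(T4) aperm(T4, c(1, 4, 3, 2))

#' Canonical MO-basis UMP2 energy (oracle)
#'
#' Independent reference path: quarter-transforms the dense AO ERI tensor to
#' the canonical MO basis and sums the textbook unrestricted MP2 energy with
#' explicit orbital-energy denominators.
#'
#' @param scf an `scf_context`
#' @return correlation energy in Hartree
#' @export
mp2_energy_canonical <- function(scf) {
  T4 <- ao_eri_dense(scf)
  mo <- list()
  for (sp in spins) {
    no <- scf$n_occ[[sp]]; C <- scf$C[[sp]]
    nv <- ncol(C) - no
    if (no == 0 || nv == 0) { mo[[sp]] <- NULL; next }
    Co <- C[, seq_len(no), drop = FALSE]
    Cv <- C[, -seq_len(no), drop = FALSE]
    t1 <- contract_mode_rect(T4, Co, 1)
    t2 <- contract_mode_rect(t1, Cv, 2)
    t3 <- contract_mode_rect(t2, Co, 3)
    mo[[sp]] <- list(iajb = contract_mode_rect(t3, Cv, 4),
                     eo = scf$eps[[sp]][seq_len(no)],
                     ev = scf$eps[[sp]][-seq_len(no)])
  }
  E <- 0
  for (sp in spins) {       # same spin
    m <- mo[[sp]]
    if (is.null(m)) next
    no <- length(m$eo); nv <- length(m$ev)
    for (i in seq_len(no)) for (j in seq_len(no)) {
      den <- outer(m$ev, m$ev, "+") - m$eo[i] - m$eo[j]
      v <- matrix(m$iajb[i, , j, ], nv)        # (ia|jb) over [a,b]
      vib_ja <- t(matrix(m$iajb[i, , j, ], nv))  # (ib|ja) over [a,b]
      E <- E - 0.5 * sum(v * (v - vib_ja) / den)
    }
  }
  # cross-spin transform
  if (!is.null(mo$alpha) && !is.null(mo$beta)) {
    Ca <- scf$C$alpha; Cb <- scf$C$beta
    noa <- scf$n_occ$alpha; nob <- scf$n_occ$beta
    t1 <- contract_mode_rect(T4, Ca[, seq_len(noa), drop = FALSE], 1)
    t2 <- contract_mode_rect(t1, Ca[, -seq_len(noa), drop = FALSE], 2)
    t3 <- contract_mode_rect(t2, Cb[, seq_len(nob), drop = FALSE], 3)
    iajb <- contract_mode_rect(t3, Cb[, -seq_len(nob), drop = FALSE], 4)
    ea_o <- scf$eps$alpha[seq_len(noa)]; ea_v <- scf$eps$alpha[-seq_len(noa)]
    eb_o <- scf$eps$beta[seq_len(nob)]; eb_v <- scf$eps$beta[-seq_len(nob)]
    for (i in seq_len(noa)) for (j in seq_len(nob)) {
      den <- outer(ea_v, eb_v, "+") - ea_o[i] - eb_o[j]
      v <- iajb[i, , j, ]
      E <- E - sum(v * v / den)
    }
  }
  E
}

# rectangular mode contraction: out[.., p, ..] = sum_i C[i, p] T[.., i, ..]
contract_mode_rect <- function(T4, C, mode) {
  d <- dim(T4)
  perm <- c(mode, setdiff(1:4, mode))
  A <- matrix(aperm(T4, perm), d[mode])
  out <- crossprod(C, A)
  d2 <- d[perm]; d2[1] <- ncol(C)
  aperm(array(out, d2), order(perm))
}

#' Dense Laplace AO-MP2 correlation energy
#'
#' Evaluates the Laplace-transformed AO-MP2 energy by contracting the
#' pseudodensity-transformed dense ERI tensor with the plain (Coulomb) and
#' crossed (exchange) ERI patterns, summed over quadrature points and spin
#' channels.
#'
#' @param scf an `scf_context`
#' @param quad a `laplace_quadrature` (or NULL for one-electron systems)
#' @return correlation energy in Hartree
#' @export
mp2_energy_laplace_dense <- function(scf, quad) {
  if (is.null(quad)) return(0)
  T4 <- ao_eri_dense(scf)
  U <- eri_exchange_view(T4)
  E <- 0
  for (kap in seq_len(quad$K)) {
    pd <- build_pseudodensities(scf, quad, kap)
    half <- list()
    for (sp in spins) {
      t1 <- contract_mode(T4, pd$Pocc[[sp]], 1)
      half[[sp]] <- contract_mode(t1, pd$Pvirt[[sp]], 2)
    }
    for (sp in spins) for (sp2 in spins) {
      Tt <- contract_mode(contract_mode(half[[sp]], pd$Pocc[[sp2]], 3),
                          pd$Pvirt[[sp2]], 4)
      E <- E - 0.5 * pd$omega * sum(Tt * T4)
      if (sp == sp2) E <- E + 0.5 * pd$omega * sum(Tt * U)
    }
  }
  E
}

#' Dense R-matrix oracle at one Laplace point
#'
#' Literal contraction of all perturbation-independent parts of the MP2
#' derivative: per spin, the matrices traced against the pseudodensity
#' derivatives.  Coulomb-like and exchange-like parts are returned
#' separately together with their combination.
#'
#' @param scf an `scf_context`
#' @param pd pseudodensities from [build_pseudodensities()]
#' @return per-spin list with `Rocc`, `Rvirt` and parts
#'   (`Rocc_C`, `Rocc_X`, `Rvirt_C`, `Rvirt_X`); total R = RC - RX
#' @export
r_dense_oracle <- function(scf, pd) {
  T4 <- ao_eri_dense(scf)
  U <- eri_exchange_view(T4)
  nb <- scf$n_bf
  w <- pd$omega
  Tm <- matrix(T4, nb)        # mode-1 matricization
  Um <- matrix(U, nb)
  out <- list()
  for (sp in spins) {
    sp2 <- setdiff(spins, sp)
    # Coulomb: DJ^{ss'}_{mm'} free in mode 1, contracted 2,3,4
    DJ <- matrix(0, nb, nb)
    for (spp in spins) {
      H <- contract_mode(contract_mode(contract_mode(
        T4, pd$Pvirt[[sp]], 2), pd$Pocc[[spp]], 3), pd$Pvirt[[spp]], 4)
      DJ <- DJ + matrix(H, nb) %*% t(Tm)
    }
    # exchange: same spin only
    HK <- contract_mode(contract_mode(contract_mode(
      T4, pd$Pvirt[[sp]], 2), pd$Pocc[[sp]], 3), pd$Pvirt[[sp]], 4)
    DK <- matrix(HK, nb) %*% t(Um)
    Rocc_C <- -w * 0.5 * (DJ + t(DJ))
    Rocc_X <- -w * 0.5 * (DK + t(DK))
    # virtual-conjugate: free index in mode 2
    DJv <- matrix(0, nb, nb)
    for (spp in spins) {
      H <- contract_mode(contract_mode(contract_mode(
        T4, pd$Pocc[[sp]], 1), pd$Pocc[[spp]], 3), pd$Pvirt[[spp]], 4)
      Hm <- matrix(aperm(H, c(2, 1, 3, 4)), nb)
      Tm2 <- matrix(aperm(T4, c(2, 1, 3, 4)), nb)
      DJv <- DJv + Hm %*% t(Tm2)
    }
    HKv <- contract_mode(contract_mode(contract_mode(
      T4, pd$Pocc[[sp]], 1), pd$Pocc[[sp]], 3), pd$Pvirt[[sp]], 4)
    Hm <- matrix(aperm(HKv, c(2, 1, 3, 4)), nb)
    Um2 <- matrix(aperm(U, c(2, 1, 3, 4)), nb)
    DKv <- Hm %*% t(Um2)
    Rvirt_C <- -w * 0.5 * (DJv + t(DJv))
    Rvirt_X <- -w * 0.5 * (DKv + t(DKv))
    out[[sp]] <- list(
      Rocc_C = Rocc_C, Rocc_X = Rocc_X,
      Rvirt_C = Rvirt_C, Rvirt_X = Rvirt_X,
      Rocc = Rocc_C - Rocc_X, Rvirt = Rvirt_C - Rvirt_X)
  }
  out$kappa <- pd$kappa
  out$provenance <- list(path = "dense", thresholds = NULL)
  out
}

# energy at one Laplace point from R matrices via the degree-4 Euler
# identity: E(k) = (1/4) sum_s ( Tr[Pocc R_occ] + Tr[Pvirt R_virt] )
laplace_point_energy_from_R <- function(pd, R) {
  e <- 0
  for (sp in spins)
    e <- e + sum(pd$Pocc[[sp]] * R[[sp]]$Rocc) +
             sum(pd$Pvirt[[sp]] * R[[sp]]$Rvirt)
  e / 4
}
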