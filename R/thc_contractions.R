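# THC fast path for the R-matrix intermediates.
#
# Coulomb-like part (per Laplace point and spin): with the grid-basis
# pseudodensities A = Xo^T Xo and B = Xv^T Xv,
#   D    = Z (A o B) Z          (precontraction, once per point/spin;
#                                Lambda-factorized as L (L^T (A o B) L) L^T)
#   RoccC  = -w X [ B o (D_a + D_b) ] X^T
#   RvirtC = -w X [ A o (D_a + D_b) ] X^T   (A and B interchanged)
#
# Exchange-like part (same spin only), batched over the occupied
# pseudo-orbital index j with w_Q = Xo[j, Q]:
#   C1 = Z diag(w) B            (shared between both parts)
#   E += C1 o C1^T              -> RoccX  = -w X E X^T
#   F += (A o C1) Z diag(w)     -> RvirtX = -w sym(X F X^T)
# Natural blocking restricts Q to {S_j} and P, R to {R_j}.
# Total R = RC - RX (same sign bookkeeping as the dense oracle).

#' Grid-basis pseudodensities
#'
#' @param Xo,Xv transformed collocation matrices of one spin (pseudo-MO x
#'   grid)
#' @return list with `A = Xo^T Xo` (occupied) and `B = Xv^T Xv` (virtual)
#' @export
grid_pseudodensities <- function(Xo, Xv) {
  list(A = crossprod(Xo), B = crossprod(Xv))
}

#' Coulomb precontraction (once per Laplace point and spin)
#'
#' @param A,B grid-basis pseudodensities
#' @param Lambda kernel factor with `Z = Lambda Lambda^T`; pass `Z` itself
#'   via `Z_direct` to bypass the factorized path
#' @param Z_direct optional unfactorized kernel (validation A/B path)
#' @return grid-basis intermediate `D`
#' @export
coulomb_precontraction <- function(A, B, Lambda, Z_direct = NULL) {
  AB <- A * B
  if (!is.null(Z_direct)) return(Z_direct %*% AB %*% Z_direct)
  Lambda %*% (crossprod(Lambda, AB) %*% Lambda) %*% t(Lambda)
}

#' Coulomb-like R contributions (Schur product + two dense multiplies)
#'
#' @param D_sum spin-summed precontraction intermediate
#' @param X AO collocation matrix
#' @param A,B grid pseudodensities of the target spin
#' @param omega Laplace weight of the point
#' @return list `RoccC`, `RvirtC`
#' @export
coulomb_R <- function(D_sum, X, A, B, omega) {
  RoccC <- -omega * X %*% (B * D_sum) %*% t(X)
  RvirtC <- -omega * X %*% (A * D_sum) %*% t(X)
  list(RoccC = 0.5 * (RoccC + t(RoccC)), RvirtC = 0.5 * (RvirtC + t(RvirtC)))
}

#' Exchange-like R contributions with natural blocking
#'
#' Joint computation of both exchange parts: the Z-containing intermediate
#' `C1 = Z diag(Xo[j,]) B` is computed once per occupied pseudo-orbital j
#' and shared.  Screening restricts the grid indices via the `{S_j}` and
#' `{R_j}` significance lists; zero thresholds (or `exact = TRUE` in the
#' config) reproduce the unscreened result exactly.
#'
#' @param Xo,Xv transformed collocations of one spin
#' @param Z THC kernel
#' @param nb an [nb_config()]
#' @param omega Laplace weight
#' @param X AO collocation matrix
#' @return list `RoccX`, `RvirtX`, and list diagnostics
#' @export
exchange_R <- function(Xo, Xv, Z, nb, omega, X) {
  ng <- ncol(Z)
  nbf <- nrow(X)
  n_occ <- nrow(Xo)
  zero <- matrix(0, nbf, nbf)
  if (n_occ == 0 || nrow(Xv) == 0)
    return(list(RoccX = zero, RvirtX = zero,
                lists = list(n_pairs_Sj = 0, n_pairs_Rj = 0)))
  lst <- nb_exchange_lists(Xo, Xv, nb)
  A <- crossprod(Xo); B <- crossprod(Xv)
  Eacc <- matrix(0, ng, ng)
  Facc <- matrix(0, ng, ng)
  for (j in seq_len(n_occ)) {
    Qs <- lst$Sj$sets[[j]]
    Rs <- lst$Rj$sets[[j]]
    if (!length(Qs) || !length(Rs)) next
    w <- Xo[j, Qs]
    C1 <- Z[Rs, Qs, drop = FALSE] %*% (w * B[Qs, Rs, drop = FALSE])
    Eacc[Rs, Rs] <- Eacc[Rs, Rs] + C1 * t(C1)
    ZW <- Z[Rs, Qs, drop = FALSE] * rep(w, each = length(Rs))
    Facc[Rs, Qs] <- Facc[Rs, Qs] +
      (A[Rs, Rs, drop = FALSE] * C1) %*% ZW
  }
  RoccX <- -omega * X %*% Eacc %*% t(X)
  RvirtX <- -omega * X %*% Facc %*% t(X)
  list(RoccX = 0.5 * (RoccX + t(RoccX)), RvirtX = 0.5 * (RvirtX + t(RvirtX)),
       lists = list(n_pairs_Sj = lst$n_pairs_Sj, n_pairs_Rj = lst$n_pairs_Rj))
}

#' THC R-matrices for all Laplace points (final joint algorithm)
#'
#' Per Laplace point and spin: one Coulomb precontraction, the Coulomb-like
#' contributions by Schur product + two multiplies, and the screened joint
#' exchange-like contributions; assembled as `R = RC - RX` with the
#' unrestricted spin-channel structure (opposite-spin enters the Coulomb
#' part only).
#'
#' @param scf an `scf_context`
#' @param thc a `thc_factorization`
#' @param quad a `laplace_quadrature`
#' @param nb an [nb_config()]
#' @param cdd_threshold pivoted-Cholesky threshold for the pseudodensities
#' @param use_lambda use the Lambda-factorized precontraction (default) or
#'   the plain Z path
#' @return list over Laplace points of per-spin R pairs, same layout as
#'   [r_dense_oracle()]
#' @export
build_R <- function(scf, thc, quad, nb = nb_config(),
                    cdd_threshold = 1e-10, use_lambda = TRUE) {
  if (is.null(quad)) return(list())
  out <- vector("list", quad$K)
  for (kap in seq_len(quad$K)) {
    t0 <- proc.time()[["elapsed"]]
    pd <- build_pseudodensities(scf, quad, kap)
    cdd <- cholesky_mos(pd, cdd_threshold)
    col <- build_collocation(thc, cdd)
    gp <- list(); D <- list()
    for (sp in spins) {
      gp[[sp]] <- grid_pseudodensities(col$Xo[[sp]], col$Xv[[sp]])
      D[[sp]] <- if (use_lambda)
        coulomb_precontraction(gp[[sp]]$A, gp[[sp]]$B, thc$Lambda)
      else
        coulomb_precontraction(gp[[sp]]$A, gp[[sp]]$B, NULL, Z_direct = thc$Z)
    }
    Dsum <- D$alpha + D$beta
    Rk <- list()
    for (sp in spins) {
      cc <- coulomb_R(Dsum, col$X, gp[[sp]]$A, gp[[sp]]$B, pd$omega)
      xx <- exchange_R(col$Xo[[sp]], col$Xv[[sp]], thc$Z, nb, pd$omega,
                       col$X)
      Rk[[sp]] <- list(
        Rocc_C = cc$RoccC, Rocc_X = xx$RoccX,
        Rvirt_C = cc$RvirtC, Rvirt_X = xx$RvirtX,
        Rocc = cc$RoccC - xx$RoccX, Rvirt = cc$RvirtC - xx$RvirtX,
        lists = xx$lists)
    }
    Rk$kappa <- kap
    Rk$provenance <- list(path = "thc", thresholds = unclass(nb),
                          use_lambda = use_lambda)
    Rk$elapsed_s <- proc.time()[["elapsed"]] - t0
    out[[kap]] <- Rk
  }
  out
}

#' Exchange-like MP2 energy contraction with natural blocking
#'
#' The prototypical exchange-like contraction of the THC-CDD-MP2 energy,
#' `sum_{PQRS} A_PR B_PS Z_PQ A_QS B_QR Z_RS`, evaluated with the same
#' per-j batching and screening as the exchange R parts; zero thresholds
#' give the unrestricted value exactly.
#'
#' @inheritParams exchange_R
#' @return scalar contraction value
#' @export
exchange_energy_nb <- function(Xo, Xv, Z, nb = nb_config()) {
  n_occ <- nrow(Xo)
  if (n_occ == 0 || nrow(Xv) == 0 || max(abs(Z)) == 0) return(0)
  lst <- nb_exchange_lists(Xo, Xv, nb)
  A <- crossprod(Xo); B <- crossprod(Xv)
  e <- 0
  for (j in seq_len(n_occ)) {
    Qs <- lst$Sj$sets[[j]]
    Rs <- lst$Rj$sets[[j]]
    if (!length(Qs) || !length(Rs)) next
    w <- Xo[j, Qs]
    C1 <- Z[Rs, Qs, drop = FALSE] %*% (w * B[Qs, Rs, drop = FALSE])
    e <- e + sum(A[Rs, Rs] * C1 * t(C1))
  }
  e
}

#' THC-MP2 correlation energy
#'
#' Evaluates the Laplace-MP2 energy with THC-factorized ERIs via the
#' degree-4 identity `E(k) = (Tr[Pocc Rocc] + Tr[Pvirt Rvirt]) / 4` from
#' the THC R-matrices.
#'
#' @inheritParams build_R
#' @return correlation energy (Hartree)
#' @export
thc_mp2_energy <- function(scf, thc, quad, nb = nb_config(exact = TRUE)) {
  if (is.null(quad)) return(0)
  Rlist <- build_R(scf, thc, quad, nb)
  e <- 0
  for (kap in seq_len(quad$K)) {
    pd <- build_pseudodensities(scf, quad, kap)
    e <- e + laplace_point_energy_from_R(pd, Rlist[[kap]])
  }
  e
}
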