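# Response machinery downstream of the R-matrices: density-expansion
# bookkeeping, the Y coupling integrals, the Fock-like intermediate,
# the Z-vector/CPSCF solution, the relaxed density, and the final
# Fermi-contact trace.
#
# Derivative structure (per spin, suppressing the spin label): with
# A_occ = tau Pocc F the occupied pseudodensity is Pocc(k) = e^{A_occ} Pocc,
# and the derivative of the correlation energy with respect to a
# basis-independent one-electron perturbation collects into
#   dE2 = sum_s Tr[dh^s W^s] + Tr[dPocc^s Xtot^s],
# where W (the explicit MP2 relaxed-density part) and Xtot (the Z-vector
# right-hand side) are built from the Y integrals
#   Y(A, B) = int_0^1 e^{uA} B e^{(1-u)A} du .
# The remaining dPocc term is converted to a Tr[dh . Dz] form by one
# unrestricted Z-vector (CPSCF) solve.

#' Coupling integral Y(A, B) by doubling recursion
#'
#' Computes `Y = int_0^1 exp(uA) B exp((1-u)A) du`, the directional
#' derivative block of the augmented matrix exponential
#' `expm([[A, B], [0, A]])`.  The recursion scales `A` down by `2^m`, sums
#' the augmented Taylor series, and applies the doubling relation
#' `Y(2t) = E(t) Y(t) + Y(t) E(t)`, `E(2t) = E(t)^2` m times.
#'
#' @param A square matrix
#' @param B square matrix (same dimension)
#' @param tau optional scale applied to `A` before solving
#' @param max_terms series-length guard
#' @return list with `Y`, `E = expm(tau A)`, `iterations` (doublings +
#'   series terms), and `residual` of the commutation identity
#'   `A Y - Y A = E B - B E` (a necessary condition of the defining
#'   integral)
#' @export
solve_Y <- function(A, B, tau = 1, max_terms = 200L) {
  A <- tau * A
  n <- nrow(A)
  if (n == 0 || max(abs(B)) == 0)
    return(list(Y = matrix(0, n, n), E = diag(n) * exp(0),
                iterations = 0L, residual = 0))
  nrmA <- norm(A, "F")
  m <- max(0L, ceiling(log2(max(nrmA, 1e-300))) + 2L)
  As <- A / 2^m; Bs <- B / 2^m
  # augmented Taylor series at scale 2^-m
  E <- diag(n); Y <- matrix(0, n, n)
  tE <- diag(n); tY <- matrix(0, n, n)
  it <- 0L
  for (k in seq_len(max_terms)) {
    new_tY <- (tE %*% Bs + tY %*% As) / k
    tE <- tE %*% As / k
    tY <- new_tY
    E <- E + tE; Y <- Y + tY
    it <- k
    if (max(abs(tE)) + max(abs(tY)) < 1e-18 * (1 + max(abs(E)) + max(abs(Y))))
      break
  }
  if (it == max_terms)
    stop("Y-series did not converge in ", max_terms,
         " terms; scaled norm(A) = ", norm(As, "F"))
  for (k in seq_len(m)) {
    Y <- E %*% Y + Y %*% E
    E <- E %*% E
  }
  res <- max(abs(A %*% Y - Y %*% A - (E %*% B - B %*% E)))
  list(Y = Y, E = E, iterations = it + m, residual = res)
}

#' Fock-like two-electron intermediate
#'
#' Builds the Coulomb + exchange contraction with an arbitrary symmetric
#' matrix pair substituting for the density:
#' `FL[s] = J[D_alpha] + J[D_beta] - K[D_s]`.  With `D = P_occ` this
#' reproduces the two-electron part of the Fock matrix.
#'
#' @param Dlike per-spin list of symmetric AO matrices
#' @param scf an `scf_context`
#' @return per-spin list of AO matrices
#' @export
build_fock_like <- function(Dlike, scf) {
  JKa <- fock_JK(scf$eri_env, Dlike$alpha)
  JKb <- fock_JK(scf$eri_env, Dlike$beta)
  Jt <- JKa$J + JKb$J
  list(alpha = Jt - JKa$K, beta = Jt - JKb$K)
}

symm <- function(M) 0.5 * (M + t(M))

#' Assemble the Z-vector right-hand side and explicit relaxed density
#'
#' Processes all Laplace points: for each spin builds the occupied/virtual
#' Y integrals from (A = tau Pocc F, B = Pocc Rocc) and
#' (A = -tau Pvirt F, B = Pvirt Rvirt), accumulates the explicit MP2
#' relaxed-density part `W` (conjugate to dh) and the occupied-density
#' conjugate `Xtot` (the CPSCF right-hand side, including the Fock-like
#' response of `W`).  No term involving the perturbation itself enters.
#'
#' @param scf an `scf_context`
#' @param quad the `laplace_quadrature` used for the R-matrices
#' @param Rlist list over Laplace points of per-spin R-matrix pairs (from
#'   [r_dense_oracle()] or [build_R()])
#' @return list with per-spin `W` (explicit part) and `rhs` (= Xtot), plus
#'   max Y residual
#' @export
assemble_rhs <- function(scf, quad, Rlist) {
  nb <- scf$n_bf
  if (length(Rlist) != quad$K)
    stop("R-matrix list has ", length(Rlist), " entries but quadrature has ",
         quad$K, " points")
  W <- list(alpha = matrix(0, nb, nb), beta = matrix(0, nb, nb))
  X <- list(alpha = matrix(0, nb, nb), beta = matrix(0, nb, nb))
  max_res <- 0
  for (kap in seq_len(quad$K)) {
    tau <- quad$tau[kap]
    R <- Rlist[[kap]]
    for (sp in spins) {
      O <- scf$P_occ[[sp]]; V <- scf$P_virt[[sp]]; Fm <- scf$F[[sp]]
      yo <- solve_Y(O %*% Fm, O %*% R[[sp]]$Rocc, tau = tau)
      yv <- solve_Y(-V %*% Fm, V %*% R[[sp]]$Rvirt, tau = tau)
      max_res <- max(max_res, yo$residual, yv$residual)
      W[[sp]] <- W[[sp]] + symm(tau * (yo$Y %*% O - yv$Y %*% V))
      X[[sp]] <- X[[sp]] + symm(tau * Fm %*% (yo$Y + yv$Y) +
                                R[[sp]]$Rocc %*% yo$E -
                                R[[sp]]$Rvirt %*% yv$E)
    }
  }
  FL <- build_fock_like(W, scf)
  list(W = W, rhs = list(alpha = X$alpha + FL$alpha,
                         beta = X$beta + FL$beta),
       y_residual = max_res)
}

# occupied-virtual vector bookkeeping -------------------------------------

ov_dims <- function(scf) {
  lapply(setNames(spins, spins), function(sp) {
    no <- scf$n_occ[[sp]]; nv <- scf$n_bf - no
    list(no = no, nv = nv, n = no * nv)
  })
}

# apply the CPSCF operator to an ov-vector u:
# (A u)_ai = (eps_a - eps_i) u_ai + [C_v^T G[Du] C_o]_ai
cpscf_apply <- function(scf, u) {
  dm <- ov_dims(scf)
  Du <- list()
  for (sp in spins) {
    no <- dm[[sp]]$no; nv <- dm[[sp]]$nv
    if (dm[[sp]]$n == 0) { Du[[sp]] <- matrix(0, scf$n_bf, scf$n_bf); next }
    Um <- matrix(u[[sp]], nv, no)
    Co <- scf$C[[sp]][, seq_len(no), drop = FALSE]
    Cv <- scf$C[[sp]][, -seq_len(no), drop = FALSE]
    M <- Cv %*% Um %*% t(Co)
    Du[[sp]] <- M + t(M)
  }
  G <- build_fock_like(Du, scf)
  out <- list()
  for (sp in spins) {
    no <- dm[[sp]]$no; nv <- dm[[sp]]$nv
    if (dm[[sp]]$n == 0) { out[[sp]] <- numeric(0); next }
    eo <- scf$eps[[sp]][seq_len(no)]; ev <- scf$eps[[sp]][-seq_len(no)]
    Co <- scf$C[[sp]][, seq_len(no), drop = FALSE]
    Cv <- scf$C[[sp]][, -seq_len(no), drop = FALSE]
    Um <- matrix(u[[sp]], nv, no)
    diagterm <- Um * outer(ev, rep(1, no)) - Um * outer(rep(1, nv), eo)
    out[[sp]] <- as.numeric(diagterm + t(Cv) %*% G[[sp]] %*% Co)
  }
  out
}

#' Z-vector / coupled-perturbed SCF solve
#'
#' Solves the unrestricted CPSCF adjoint equation `A z = b` in the
#' occupied-virtual space, where `b_ai = 2 [C_v^T rhs C_o]_ai` and `A` is
#' the (symmetric, positive-definite at a stable SCF) orbital-rotation
#' Hessian.  Returns the response density `Dz` such that for any symmetric
#' one-electron perturbation `dh`, `Tr[dPocc rhs] = Tr[dh Dz]`.
#' The solution is verified by re-applying the operator; the residual
#' max-norm must fall below `conv`.
#'
#' @param rhs per-spin symmetric AO matrices (the assembled right-hand
#'   side)
#' @param scf an `scf_context`
#' @param conv convergence/verification threshold (residual max-norm)
#' @return list with per-spin response density `Dz`, the ov-vector `z`,
#'   the verified `residual`, and solver diagnostics
#' @export
solve_cpscf <- function(rhs, scf, conv = 1e-4) {
  dm <- ov_dims(scf)
  b <- list()
  for (sp in spins) {
    no <- dm[[sp]]$no; nv <- dm[[sp]]$nv
    if (dm[[sp]]$n == 0) { b[[sp]] <- numeric(0); next }
    Co <- scf$C[[sp]][, seq_len(no), drop = FALSE]
    Cv <- scf$C[[sp]][, -seq_len(no), drop = FALSE]
    b[[sp]] <- as.numeric(2 * t(Cv) %*% rhs[[sp]] %*% Co)
  }
  ntot <- sum(vapply(dm, function(d) d$n, 0))
  if (ntot == 0) {
    Dz <- lapply(dm, function(d) matrix(0, scf$n_bf, scf$n_bf))
    names(Dz) <- spins
    return(list(Dz = Dz, z = b, residual = 0, method = "empty",
                history = numeric(0)))
  }
  pack <- function(u) c(u$alpha, u$beta)
  unpack <- function(v) list(alpha = v[seq_len(dm$alpha$n)],
                             beta = v[dm$alpha$n + seq_len(dm$beta$n)])
  bv <- pack(b)
  applyA <- function(v) pack(cpscf_apply(scf, unpack(v)))
  history <- numeric(0)
  if (ntot <= 800) {
    M <- vapply(seq_len(ntot), function(j) {
      e <- numeric(ntot); e[j] <- 1; applyA(e)
    }, numeric(ntot))
    # pseudo-inverse solve: rotations among exactly degenerate partially
    # occupied orbitals give zero modes of the orbital Hessian; a
    # compatible right-hand side has no weight there, and the residual
    # verification below catches any genuine inconsistency
    es <- eigen(0.5 * (M + t(M)), symmetric = TRUE)
    keep <- abs(es$values) > 1e-10 * max(abs(es$values))
    zv <- es$vectors[, keep, drop = FALSE] %*%
      ((t(es$vectors[, keep, drop = FALSE]) %*% bv) / es$values[keep])
    zv <- as.numeric(zv)
    method <- "dense"
  } else {
    # conjugate gradient on the SPD system
    zv <- numeric(ntot)
    r <- bv - applyA(zv); p <- r
    rs <- sum(r * r)
    for (it in seq_len(500L)) {
      Ap <- applyA(p)
      al <- rs / sum(p * Ap)
      zv <- zv + al * p
      r <- r - al * Ap
      rs_new <- sum(r * r)
      history <- c(history, max(abs(r)))
      if (max(abs(r)) < 0.1 * conv) break
      p <- r + (rs_new / rs) * p
      rs <- rs_new
    }
    method <- "cg"
  }
  res <- max(abs(applyA(zv) - bv))
  if (res > conv)
    stop("CPSCF residual ", format(res), " above conv = ", conv,
         "; history: ", paste(format(tail(history, 5)), collapse = ", "))
  z <- unpack(zv)
  Dz <- list()
  for (sp in spins) {
    no <- dm[[sp]]$no; nv <- dm[[sp]]$nv
    if (dm[[sp]]$n == 0) { Dz[[sp]] <- matrix(0, scf$n_bf, scf$n_bf); next }
    Zm <- matrix(z[[sp]], nv, no)
    M <- scf$C[[sp]][, -seq_len(no), drop = FALSE] %*% Zm %*%
      t(scf$C[[sp]][, seq_len(no), drop = FALSE])
    Dz[[sp]] <- -0.5 * (M + t(M))
  }
  list(Dz = Dz, z = z, residual = res, method = method, history = history)
}

#' Relaxed one-particle density of the Laplace-MP2 derivative
#'
#' Combines the explicit MP2 part and the Z-vector response part into the
#' effective density whose trace with a spin-dependent one-electron
#' perturbation yields the MP2 correction to the energy derivative.
#'
#' @param scf an `scf_context`
#' @param quad the Laplace quadrature
#' @param Rlist per-point R matrices (dense oracle or THC path)
#' @param cpscf_conv CPSCF verification threshold
#' @return list of class `relaxed_density` with per-spin `explicit`,
#'   `response`, `total`, and diagnostics
#' @export
mp2_relaxed_density <- function(scf, quad, Rlist, cpscf_conv = 1e-4) {
  nb <- scf$n_bf
  zero <- list(alpha = matrix(0, nb, nb), beta = matrix(0, nb, nb))
  if (is.null(quad) || length(Rlist) == 0) {
    out <- list(explicit = zero, response = zero, total = zero,
                y_residual = 0, cpscf = list(residual = 0, method = "none"))
    class(out) <- "relaxed_density"
    return(out)
  }
  asm <- assemble_rhs(scf, quad, Rlist)
  cp <- solve_cpscf(asm$rhs, scf, conv = cpscf_conv)
  tot <- list(alpha = asm$W$alpha + cp$Dz$alpha,
              beta = asm$W$beta + cp$Dz$beta)
  out <- list(explicit = asm$W, response = cp$Dz, total = tot,
              y_residual = asm$y_residual,
              cpscf = cp[c("residual", "method")])
  class(out) <- "relaxed_density"
  out
}

#' Isotropic hyperfine coupling constant of one nucleus
#'
#' Traces the Fermi-contact operator with the SCF spin density and with the
#' relaxed MP2 spin density, converting to MHz with CODATA constants and
#' the tabulated nuclear g-factor of the element's most abundant magnetic
#' isotope.
#'
#' @param scf an `scf_context`
#' @param relaxed a `relaxed_density` (or NULL for SCF only)
#' @param k nucleus index
#' @return list of class `hfcc_result`: `element`, `isotope`, and
#'   `A_iso_SCF`, `A_iso_MP2`, `A_iso_total` in MHz
#' @export
compute_hfcc <- function(scf, relaxed, k) {
  fc <- fermi_contact_integrals(scf, k)
  el <- scf$mol$symbols[k]
  gf <- isotope_g_factor(el)
  pref <- .fc_prefactor_mhz * gf$g
  a_scf <- pref * sum(fc$H_FC * (scf$P_occ$alpha - scf$P_occ$beta))
  a_mp2 <- if (is.null(relaxed)) 0 else
    pref * sum(fc$H_FC * (relaxed$total$alpha - relaxed$total$beta))
  structure(list(nucleus = k, element = el, isotope = gf$isotope,
                 g_factor = gf$g,
                 A_iso_SCF = a_scf, A_iso_MP2 = a_mp2,
                 A_iso_total = a_scf + a_mp2),
            class = "hfcc_result")
}

#' @export
print.hfcc_result <- function(x, ...) {
  cat(sprintf("%s(%s) nucleus %d: A_iso = %.4f MHz (SCF %.4f + MP2 %.4f)\n",
              x$element, x$isotope, x$nucleus, x$A_iso_total, x$A_iso_SCF,
              x$A_iso_MP2))
  invisible(x)
}
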