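# Engine adapter: all raw quantum-chemical quantities (integrals, SCF
# solution, basis values on points) are produced here; every other module is
# isolated from the integral backend.

#' Converged unrestricted SCF context
#'
#' Runs an unrestricted Hartree-Fock calculation (also for closed shells)
#' and collects everything downstream modules need: overlap and core
#' Hamiltonian, per-spin Fock matrices, MO coefficients and energies,
#' occupied/virtual density matrices, and the dense AO ERI tensor (guarded
#' by size).
#'
#' @param mol a [molecule()]
#' @param basis orbital basis name
#' @param aux_basis auxiliary basis name ("autoaux")
#' @param conv list of thresholds: `energy` (Hartree), `commutator`
#' @param h_alpha,h_beta optional extra one-electron operators added to the
#'   core Hamiltonian of the respective spin channel (used by the
#'   finite-difference oracle)
#' @param eri_guard maximum basis size for which the dense ERI tensor is kept
#' @return an object of class `scf_context`
#' @export
build_scf_context <- function(mol, basis = "sto-3g", aux_basis = "autoaux",
                              conv = list(energy = 1e-8, commutator = 1e-7),
                              h_alpha = NULL, h_beta = NULL,
                              eri_guard = 48L) {
  shells <- basis_shells(mol, basis)
  nb <- n_basis_functions(shells)
  if (nb > eri_guard)
    stop("basis size ", nb, " exceeds the dense-ERI guard (", eri_guard, ")")
  xyz <- mol_coords_bohr(mol)
  one <- cpp_one_electron(shells, xyz, as.numeric(mol$Z))
  eri <- cpp_eri_dense(shells, -1.0)
  eri_env <- make_eri_env(eri)
  hcore <- one$T + one$V
  res <- uhf_scf(mol, shells, eri_env, one$S, hcore,
                 h_alpha = h_alpha, h_beta = h_beta,
                 conv_energy = conv$energy, conv_comm = conv$commutator)
  Sinv <- {
    X <- sym_inv_sqrt(one$S)
    X %*% t(X)
  }
  P_occ <- res$D
  P_virt <- lapply(P_occ, function(D) Sinv - D)
  structure(list(
    mol = mol, basis = basis, aux_basis = aux_basis, shells = shells,
    n_bf = nb, S = one$S, S_inv = Sinv, h = hcore, T_kin = one$T,
    V_nuc = one$V,
    h_spin = list(alpha = hcore + if (is.null(h_alpha)) 0 else h_alpha,
                  beta  = hcore + if (is.null(h_beta)) 0 else h_beta),
    F = res$F, C = res$C, eps = res$eps,
    P_occ = P_occ, P_virt = P_virt,
    n_occ = list(alpha = mol$n_alpha, beta = mol$n_beta),
    E_SCF = res$E, E_nuc = nuclear_repulsion(mol),
    scf_iterations = res$n_iter, scf_commutator = res$comm,
    eri_env = eri_env,
    metadata = list(angular = "cartesian, lx-major lexicographic",
                    normalization = "component-wise contracted")
  ), class = "scf_context")
}

#' @export
print.scf_context <- function(x, ...) {
  cat(sprintf(
    "scf_context: %s/%s, %d basis functions, E_SCF = %.10f Ha (%d iter)\n",
    x$basis, x$aux_basis, x$n_bf, x$E_SCF, x$scf_iterations))
  invisible(x)
}

spins <- c("alpha", "beta")

#' Fermi-contact operator matrix
#'
#' The isotropic hyperfine interaction probes the spin density at the
#' nucleus; in a point-nucleus model its AO matrix is the outer product of
#' the basis-function value vector at the nuclear position with itself:
#' `H_FC[mu, nu] = chi_mu(R_k) chi_nu(R_k)` (rank one, PSD).
#'
#' @param scf an `scf_context`
#' @param k nucleus index (1-based)
#' @return list with the matrix `H_FC`, the value vector `chi`, and `k`
#' @export
fermi_contact_integrals <- function(scf, k) {
  xyz <- mol_coords_bohr(scf$mol)
  stopifnot(k >= 1, k <= nrow(xyz))
  chi <- as.numeric(cpp_collocate(scf$shells, xyz[k, , drop = FALSE]))
  list(k = k, chi = chi, H_FC = outer(chi, chi))
}

#' Dense AO ERI tensor
#'
#' Four-index tensor `(mu nu | la si)` in chemists' notation, for oracle
#' contractions on small systems.
#'
#' @param scf an `scf_context`
#' @return 4-dimensional array
#' @export
ao_eri_dense <- function(scf) {
  array(scf$eri_env$Mj, dim = rep(scf$n_bf, 4))
}

#' Density-fitting factors
#'
#' Three-index factors `B[alpha, mu, nu]` with
#' `(mu nu | la si) ~ sum_alpha B[alpha, mu, nu] B[alpha, la, si]`.
#' Under the plain Coulomb metric `B = V^{-1/2} T` with `V` the two-centre
#' Coulomb matrix and `T` the three-centre integrals.  Under the attenuated
#' Coulomb metric the fit coefficients are determined with the short-range
#' kernel `erfc(w r)/r` (locality increases with `w`; `w -> 0` recovers the
#' Coulomb metric) and recombined with the full Coulomb two-centre matrix:
#' `B = V^{1/2} M(w)^{-1} T(w)`.
#'
#' @param scf an `scf_context`
#' @param metric "coulomb" or "attenuated"
#' @param omega attenuation strength for the attenuated metric
#' @param cond_tol relative eigenvalue cutoff for the metric pseudo-inverse
#' @return list with `B` (n_aux x n_bf x n_bf array), metric record, and the
#'   metric condition number
#' @export
ri_factors <- function(scf, metric = c("attenuated", "coulomb"),
                       omega = 0.1, cond_tol = 1e-12) {
  metric <- match.arg(metric)
  aux <- autoaux_shells(scf$mol, scf$basis)
  naux <- n_basis_functions(aux)
  V <- cpp_eri_2c(aux, -1.0)
  psqrt <- function(M, pw) {
    e <- eigen(0.5 * (M + t(M)), symmetric = TRUE)
    keep <- e$values > cond_tol * max(e$values)
    list(mat = e$vectors[, keep, drop = FALSE] %*%
           (t(e$vectors[, keep, drop = FALSE]) * e$values[keep]^pw),
         cond = max(e$values) / min(e$values[keep]))
  }
  if (metric == "coulomb") {
    Tc <- cpp_eri_3c(scf$shells, aux, -1.0)
    Vh <- psqrt(V, -0.5)
    Bm <- Vh$mat %*% t(matrix(Tc, scf$n_bf^2, naux))
    cond <- Vh$cond
  } else {
    stopifnot(omega > 0)
    # short-range (erfc) kernel integrals: full Coulomb minus erf part
    Tw <- cpp_eri_3c(scf$shells, aux, -1.0) - cpp_eri_3c(scf$shells, aux, omega)
    Mw <- V - cpp_eri_2c(aux, omega)
    Mi <- psqrt(Mw, -1)
    Vh <- psqrt(V, 0.5)
    Bm <- Vh$mat %*% Mi$mat %*% t(matrix(Tw, scf$n_bf^2, naux))
    cond <- Mi$cond
  }
  list(B = array(Bm, c(nrow(Bm), scf$n_bf, scf$n_bf)),
       metric = metric, omega = if (metric == "attenuated") omega else NA,
       n_aux = nrow(Bm), condition = cond, aux_shells = aux)
}

#' Basis-function values at points
#'
#' @param scf an `scf_context`
#' @param points n x 3 matrix of Cartesian points (bohr)
#' @return `n_bf x n` matrix; column p holds all basis values at point p
#' @export
collocate <- function(scf, points) {
  cpp_collocate(scf$shells, matrix(points, ncol = 3))
}

# reconstruct ERIs from RI factors (oracle helper)
ri_reconstruct_eri <- function(ri) {
  nb <- dim(ri$B)[2]
  Bm <- matrix(ri$B, ri$n_aux, nb * nb)
  array(crossprod(Bm), dim = rep(nb, 4))
}
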