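# Unrestricted Hartree-Fock with DIIS acceleration.
#
# The SCF layer always uses the unrestricted formalism, also for closed
# shells, so that spin-symmetry properties are expressible downstream.
# Fock matrices are built from the dense AO ERI tensor; fixture systems are
# small enough that this is the fastest and most transparent route.

sym_inv_sqrt <- function(S, tol = 1e-10) {
  e <- eigen(S, symmetric = TRUE)
  keep <- e$values > tol * max(e$values)
  e$vectors[, keep, drop = FALSE] %*%
    (t(e$vectors[, keep, drop = FALSE]) / sqrt(e$values[keep]))
}

# Coulomb and exchange builds from the dense ERI tensor.
# J[D]_mn = sum_ls (mn|ls) D_ls ; K[D]_mn = sum_ls (ml|ns) D_ls
fock_JK <- function(eri_env, D) {
  nb <- nrow(D)
  J <- matrix(eri_env$Mj %*% as.vector(D), nb)
  K <- matrix(eri_env$Mk %*% as.vector(D), nb)
  list(J = 0.5 * (J + t(J)), K = 0.5 * (K + t(K)))
}

# environment holding matricized ERI views (shared, built once)
make_eri_env <- function(eri) {
  nb <- dim(eri)[1]
  env <- new.env(parent = emptyenv())
  env$nb <- nb
  env$Mj <- matrix(eri, nb * nb, nb * nb)
  env$Mk <- matrix(aperm(eri, c(1, 3, 2, 4)), nb * nb, nb * nb)
  env
}

uhf_scf <- function(mol, shells, eri_env, S, hcore,
                    h_alpha = NULL, h_beta = NULL,
                    conv_energy = 1e-8, conv_comm = 1e-7,
                    max_iter = 300L, diis_dim = 8L) {
  nb <- nrow(S)
  nocc <- c(alpha = mol$n_alpha, beta = mol$n_beta)
  h <- list(alpha = hcore + if (is.null(h_alpha)) 0 else h_alpha,
            beta  = hcore + if (is.null(h_beta)) 0 else h_beta)
  X <- sym_inv_sqrt(S)
  Enuc <- nuclear_repulsion(mol)

  solve_fock <- function(F) {
    Ft <- t(X) %*% F %*% X
    e <- eigen(0.5 * (Ft + t(Ft)), symmetric = TRUE)
    ord <- order(e$values)  # eigen() sorts decreasing; aufbau needs ascending
    list(C = X %*% e$vectors[, ord, drop = FALSE], eps = e$values[ord])
  }
  dens <- function(orb, n) {
    if (n == 0) return(matrix(0, nb, nb))
    Co <- orb$C[, seq_len(n), drop = FALSE]
    Co %*% t(Co)
  }

  orb <- lapply(h, solve_fock)
  D <- list(alpha = dens(orb$alpha, nocc[1]), beta = dens(orb$beta, nocc[2]))
  E_old <- Inf
  trace <- numeric(0)
  diis_F <- list(); diis_e <- list()
  F <- D  # placeholder shapes
  for (it in seq_len(max_iter)) {
    JKa <- fock_JK(eri_env, D$alpha)
    JKb <- fock_JK(eri_env, D$beta)
    Jtot <- JKa$J + JKb$J
    F <- list(alpha = h$alpha + Jtot - JKa$K,
              beta  = h$beta  + Jtot - JKb$K)
    E <- Enuc + 0.5 * sum(D$alpha * (h$alpha + F$alpha)) +
                0.5 * sum(D$beta  * (h$beta  + F$beta))
    err <- lapply(c("alpha", "beta"), function(sp) {
      e <- F[[sp]] %*% D[[sp]] %*% S - S %*% D[[sp]] %*% F[[sp]]
      t(X) %*% e %*% X
    })
    comm <- max(abs(unlist(err)))
    trace <- c(trace, E)
    if (abs(E - E_old) < conv_energy && comm < conv_comm) {
      orb <- lapply(F, solve_fock)
      return(list(converged = TRUE, n_iter = it, E = E, F = F,
                  C = list(alpha = orb$alpha$C, beta = orb$beta$C),
                  eps = list(alpha = orb$alpha$eps, beta = orb$beta$eps),
                  D = D, comm = comm, trace = trace))
    }
    E_old <- E
    # DIIS extrapolation
    diis_F[[length(diis_F) + 1]] <- F
    diis_e[[length(diis_e) + 1]] <- c(err[[1]], err[[2]])
    if (length(diis_F) > diis_dim) {
      diis_F <- diis_F[-1]; diis_e <- diis_e[-1]
    }
    m <- length(diis_F)
    if (m >= 2) {
      B <- matrix(0, m + 1, m + 1)
      for (i in 1:m) for (j in 1:m)
        B[i, j] <- sum(diis_e[[i]] * diis_e[[j]])
      B[m + 1, 1:m] <- B[1:m, m + 1] <- -1
      rhs <- c(numeric(m), -1)
      cf <- tryCatch(solve(B, rhs)[1:m], error = function(e) NULL)
      if (!is.null(cf) && all(is.finite(cf))) {
        Fa <- Reduce(`+`, Map(function(w, f) w * f$alpha, cf, diis_F))
        Fb <- Reduce(`+`, Map(function(w, f) w * f$beta, cf, diis_F))
        F <- list(alpha = Fa, beta = Fb)
      }
    }
    orb <- lapply(F, solve_fock)
    D <- list(alpha = dens(orb$alpha, nocc[1]), beta = dens(orb$beta, nocc[2]))
  }
  stop("SCF failed to converge in ", max_iter,
       " iterations; energy trace tail: ",
       paste(sprintf("%.10f", tail(trace, 5)), collapse = ", "))
}
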