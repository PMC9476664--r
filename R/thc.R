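# Least-squares tensor hypercontraction of the AO ERIs:
#   (mu nu | la si) ~ sum_PQ X_muP X_nuP Z_PQ X_laQ X_siQ
# with X the basis values on a real-space grid and Z fitted by the normal
# equations Z = S+ W S+, S_PQ = (X^T X)_PQ^2 (Hadamard square), W the ERI
# projected onto grid product functions.  Grid points are selected from an
# atom-centred parent quadrature by pivoted Cholesky of the grid-metric
# Gram matrix.

# Lebedev angular set, 26 points (octahedron + cube + cuboctahedron)
.lebedev26 <- function() {
  a1 <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
              c(0, 0, 1), c(0, 0, -1))
  s3 <- 1 / sqrt(3)
  a3 <- as.matrix(expand.grid(c(-s3, s3), c(-s3, s3), c(-s3, s3)))
  s2 <- 1 / sqrt(2)
  a2 <- rbind(
    cbind(0, c(s2, s2, -s2, -s2), c(s2, -s2, s2, -s2)),
    cbind(c(s2, s2, -s2, -s2), 0, c(s2, -s2, s2, -s2)),
    cbind(c(s2, s2, -s2, -s2), c(s2, -s2, s2, -s2), 0))
  list(points = rbind(a1, a2, a3),
       weights = c(rep(1 / 21, 6), rep(4 / 105, 12), rep(9 / 280, 8)))
}

# per-element radial scale (bohr) for the Handy radial map
.radial_scale <- c(H = 1.0, He = 0.8, B = 1.6, C = 1.4, N = 1.3, O = 1.2,
                   F = 1.1, P = 1.8)

# atom-centred parent grid: n_rad Handy radial shells x Lebedev 26
parent_grid <- function(mol, n_rad = 12L) {
  leb <- .lebedev26()
  xyz <- mol_coords_bohr(mol)
  pts <- NULL; wts <- NULL; atom <- integer(0)
  for (ia in seq_along(mol$symbols)) {
    Rm <- .radial_scale[[mol$symbols[ia]]]
    if (is.null(Rm)) Rm <- 1.4
    i <- seq_len(n_rad)
    x <- i / (n_rad + 1)
    r <- Rm * (x / (1 - x))^2
    drdx <- Rm * 2 * x / (1 - x)^3
    wr <- r^2 * drdx / (n_rad + 1)
    for (k in seq_len(n_rad)) {
      pk <- leb$points * r[k]
      pk <- sweep(pk, 2, xyz[ia, ], "+")
      pts <- rbind(pts, pk)
      wts <- c(wts, 4 * pi * leb$weights * wr[k])
      atom <- c(atom, rep(ia, nrow(pk)))
    }
  }
  list(points = pts, weights = wts, atom = atom)
}

#' Build a THC grid by pivoted-Cholesky pruning of a parent grid
#'
#' Points are selected from an atom-centred parent quadrature grid by
#' pivoted Cholesky of the grid-metric Gram matrix
#' `S_PQ = (sum_mu X_muP X_muQ)^2`, stopping at
#' `N_grid = target_ratio * N_aux`, then sorted spatially (atom block,
#' then pivot order within the block).
#'
#' @param scf an `scf_context`
#' @param target_ratio grid size as a multiple of the auxiliary-basis size
#' @param n_rad radial shells of the parent grid per atom
#' @param n_aux auxiliary basis size (default: from [autoaux_shells()]);
#'   `target_n` overrides the product entirely
#' @param target_n explicit number of grid points (use `Inf` for the whole
#'   parent grid)
#' @return list of class `thc_grid`: `points` (bohr), `weights`, `atom`,
#'   `ordering`, `n_grid`
#' @export
build_thc_grid <- function(scf, target_ratio = 3, n_rad = 12L,
                           n_aux = NULL, target_n = NULL) {
  pg <- parent_grid(scf$mol, n_rad)
  if (is.null(target_n)) {
    if (is.null(n_aux))
      n_aux <- n_basis_functions(autoaux_shells(scf$mol, scf$basis))
    target_n <- round(target_ratio * n_aux)
  }
  npar <- nrow(pg$points)
  if (target_n > npar)
    stop("parent grid (", npar, " points) smaller than target (",
         target_n, "); increase n_rad")
  X <- collocate(scf, pg$points)
  G <- crossprod(X)
  S <- G * G
  L <- pivoted_cholesky(S, threshold = 1e-14 * max(diag(S)),
                        max_rank = min(target_n, npar))
  piv <- attr(L, "pivots")
  sel <- piv[seq_len(min(target_n, length(piv)))]
  if (length(sel) < target_n) {
    # Gram rank exhausted before the target size: pad with the remaining
    # parent points of largest product weight (improves the conditioning
    # of the least-squares fit on over-complete grids)
    rest <- setdiff(order(diag(S), decreasing = TRUE), sel)
    sel <- c(sel, rest[seq_len(min(target_n - length(sel), length(rest)))])
  }
  # drop (near-)duplicate points
  P <- pg$points[sel, , drop = FALSE]
  keep <- rep(TRUE, nrow(P))
  if (nrow(P) > 1) {
    for (i in 2:nrow(P)) {
      d2 <- rowSums((P[seq_len(i - 1), , drop = FALSE] -
                       matrix(P[i, ], i - 1, 3, byrow = TRUE))^2)
      if (min(d2) < 1e-16) keep[i] <- FALSE
    }
  }
  sel <- sel[keep]
  # spatial sort: atom block, then pivot order within the block
  ord <- order(pg$atom[sel], seq_along(sel))
  sel <- sel[ord]
  structure(list(points = pg$points[sel, , drop = FALSE],
                 weights = pg$weights[sel], atom = pg$atom[sel],
                 ordering = ord, n_grid = length(sel),
                 parent_size = npar),
            class = "thc_grid")
}

# regularized pseudo-inverse via symmetric eigendecomposition
pinv_sym <- function(M, rel_tol = 1e-10) {
  e <- eigen(0.5 * (M + t(M)), symmetric = TRUE)
  keep <- e$values > rel_tol * max(abs(e$values))
  if (!any(keep)) stop("pseudo-inverse: all eigenvalues below cutoff")
  list(inv = e$vectors[, keep, drop = FALSE] %*%
         (t(e$vectors[, keep, drop = FALSE]) / e$values[keep]),
       cond = max(e$values) / min(e$values[keep]),
       rank = sum(keep))
}

# column-paired collocation: Xp[mu nu, P] = X[mu,P] X[nu,P]
pair_collocation <- function(X) {
  nb <- nrow(X)
  out <- matrix(0, nb * nb, ncol(X))
  for (p in seq_len(ncol(X))) out[, p] <- as.numeric(outer(X[, p], X[, p]))
  out
}

#' Fit the THC kernel matrix Z
#'
#' Solves the LS-THC normal equations `Z = S+ W S+` with
#' `S = (X^T X) o (X^T X)` and `W` the ERI projection onto grid product
#' functions, either through density-fitting factors (`ri`) or from the
#' dense ERI tensor (`eri`, exact-projection oracle).  Schwarz screening
#' drops negligible AO product pairs from the projection.
#'
#' @param X collocation matrix (n_bf x n_grid)
#' @param ri factors from [ri_factors()] (used if `eri` is NULL)
#' @param eri dense ERI tensor for the exact projection
#' @param regularization relative eigenvalue cutoff of the Gram
#'   pseudo-inverse
#' @param schwarz_tol relative Schwarz screening threshold for AO pairs
#' @return list with `Z` (symmetrized), Gram condition number and rank,
#'   and the fitting metric record
#' @export
fit_Z <- function(X, ri = NULL, eri = NULL, regularization = 1e-10,
                  schwarz_tol = 1e-12) {
  nb <- nrow(X)
  ng_full <- ncol(X)
  # exclude points where every basis product underflows (they carry no
  # information and would poison the preconditioner)
  act <- colSums(X^2)^2 > 1e-30 * max(colSums(X^2)^2)
  X <- X[, act, drop = FALSE]
  Xp <- pair_collocation(X)
  S <- crossprod(X)^2
  # Jacobi preconditioning: normalize grid product functions so the
  # pseudo-inverse cutoff treats all points on the same scale
  dj <- 1 / sqrt(pmax(diag(S), 1e-300))
  Sp <- pinv_sym(dj * t(dj * S), regularization)
  if (Sp$cond > 1e14)
    stop("THC Gram matrix condition ", format(Sp$cond),
         " too large; increase regularization or reduce the grid")
  if (!is.null(eri)) {
    W <- crossprod(Xp, matrix(eri, nb * nb, nb * nb)) %*% Xp
    metric <- list(source = "dense", metric = "coulomb", omega = NA)
  } else {
    stopifnot(!is.null(ri))
    Bm <- matrix(ri$B, ri$n_aux, nb * nb)
    # Schwarz screen on AO pairs via the RI diagonal
    q <- sqrt(pmax(colSums(Bm^2), 0))
    mask <- q > schwarz_tol * max(q)
    E <- Bm[, mask, drop = FALSE] %*% Xp[mask, , drop = FALSE]
    W <- crossprod(E)
    metric <- list(source = "ri", metric = ri$metric, omega = ri$omega,
                   schwarz_kept = sum(mask), schwarz_total = length(mask))
  }
  Wt <- dj * t(dj * W)
  Za <- dj * t(dj * (Sp$inv %*% Wt %*% Sp$inv))
  Z <- matrix(0, ng_full, ng_full)
  Z[act, act] <- 0.5 * (Za + t(Za))
  list(Z = Z, gram_condition = Sp$cond,
       gram_rank = Sp$rank, metric = metric, n_active = sum(act))
}

#' Factorize the THC kernel as Z = Lambda Lambda^T
#'
#' Symmetric eigendecomposition with clamping: eigenvalues below
#' `clamp * max(|lambda|)` (including all negatives beyond noise) are
#' discarded; `Lambda = U sqrt(lambda_kept)`.
#'
#' @param Z symmetric kernel matrix
#' @param clamp relative clamping threshold
#' @return list with `Lambda`, `clamp_report` (counts and the most
#'   negative discarded eigenvalue), and `Z_psd = Lambda Lambda^T`
#' @export
factorize_Z <- function(Z, clamp = 1e-12) {
  e <- eigen(0.5 * (Z + t(Z)), symmetric = TRUE)
  lmax <- max(abs(e$values))
  keep <- e$values > clamp * lmax
  if (!any(keep)) stop("all eigenvalues clamped: degenerate factorization")
  Lambda <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(e$values[keep]), sum(keep))
  list(Lambda = Lambda,
       clamp_report = list(
         n_kept = sum(keep), n_discarded = sum(!keep),
         most_negative = if (any(e$values < 0)) min(e$values) else 0,
         lambda_max = lmax),
       Z_psd = tcrossprod(Lambda))
}

#' Full THC factorization of an SCF context
#'
#' Convenience driver: builds the grid, collocation, RI factors (unless a
#' dense exact projection is requested), fits Z and factorizes it.
#'
#' @param scf an `scf_context`
#' @param target_ratio grid ratio relative to the auxiliary basis
#' @param metric "attenuated" or "coulomb" (fitting metric of the RI step)
#' @param omega attenuation strength
#' @param eri_source "ri" or "dense" (exact projection, oracle use)
#' @param grid optional pre-built `thc_grid`
#' @param n_rad parent-grid radial shells
#' @return list of class `thc_factorization` with `X`, `Z`, `Lambda`,
#'   `grid`, diagnostics
#' @export
build_thc <- function(scf, target_ratio = 3, metric = "attenuated",
                      omega = 0.1, eri_source = c("ri", "dense"),
                      grid = NULL, n_rad = 12L) {
  eri_source <- match.arg(eri_source)
  if (is.null(grid))
    grid <- build_thc_grid(scf, target_ratio = target_ratio, n_rad = n_rad)
  X <- collocate(scf, grid$points)
  if (eri_source == "dense") {
    fz <- fit_Z(X, eri = ao_eri_dense(scf))
    ri <- NULL
  } else {
    ri <- ri_factors(scf, metric = metric, omega = omega)
    fz <- fit_Z(X, ri = ri)
  }
  fac <- factorize_Z(fz$Z)
  sparsity <- mean(abs(X) < 1e-10)
  structure(list(X = X, Z = fz$Z, Lambda = fac$Lambda,
                 Z_psd = fac$Z_psd, grid = grid,
                 clamp_report = fac$clamp_report,
                 gram_condition = fz$gram_condition,
                 metric = fz$metric, n_aux = if (is.null(ri)) NA else
                   ri$n_aux,
                 collocation_sparsity = sparsity),
            class = "thc_factorization")
}

#' @export
print.thc_factorization <- function(x, ...) {
  cat(sprintf(
    "thc_factorization: %d grid points, metric %s, gram cond %.2e, %d clamped\n",
    x$grid$n_grid, x$metric$metric, x$gram_condition,
    x$clamp_report$n_discarded))
  invisible(x)
}

#' Transformed collocation matrices for one Laplace point
#'
#' `Xo = Locc^T X`, `Xv = Lvirt^T X`: collocations in the occupied and
#' virtual Cholesky pseudo-MO bases.
#'
#' @param thc a `thc_factorization` (or plain collocation matrix)
#' @param cdd Cholesky pseudo-MOs from [cholesky_mos()]
#' @return per-spin lists `Xo`, `Xv` plus the AO collocation `X`
#' @export
build_collocation <- function(thc, cdd) {
  X <- if (is.matrix(thc)) thc else thc$X
  out <- list(X = X, Xo = list(), Xv = list())
  for (sp in spins) {
    out$Xo[[sp]] <- crossprod(cdd$Locc[[sp]], X)
    out$Xv[[sp]] <- crossprod(cdd$Lvirt[[sp]], X)
  }
  out
}

#' Reconstruct ERI elements from a THC factorization
#'
#' @param thc a `thc_factorization`
#' @param mu,nu,la,si AO indices (vectors of equal length, recycled)
#' @return numeric vector `sum_PQ X_muP X_nuP Z_PQ X_laQ X_siQ`
#' @export
reconstruct_eri <- function(thc, mu, nu, la, si) {
  n <- max(length(mu), length(nu), length(la), length(si))
  mu <- rep_len(mu, n); nu <- rep_len(nu, n)
  la <- rep_len(la, n); si <- rep_len(si, n)
  vapply(seq_len(n), function(i) {
    xb <- thc$X[mu[i], ] * thc$X[nu[i], ]
    xk <- thc$X[la[i], ] * thc$X[si[i], ]
    as.numeric(xb %*% thc$Z %*% xk)
  }, 0)
}

#' Serialize a THC factorization to a single container file
#'
#' Stores all matrices and metadata for reuse across runs.
#'
#' @param thc a `thc_factorization`
#' @param path file path
#' @export
thc_save <- function(thc, path) saveRDS(thc, path)

#' @rdname thc_save
#' @export
thc_load <- function(path) {
  obj <- readRDS(path)
  stopifnot(inherits(obj, "thc_factorization"))
  obj
}

# full THC ERI tensor (small systems)
thc_eri_tensor <- function(thc) {
  nb <- nrow(thc$X)
  Xp <- pair_collocation(thc$X)
  array(Xp %*% thc$Z %*% t(Xp), dim = rep(nb, 4))
}
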