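# Laplace quadrature of the orbital-energy denominator, pseudodensities,
# and their pivoted Cholesky decomposition into pseudo-MO coefficients.
#
# The reciprocal 1/x on [x_min, x_max] is expanded as
#   1/x ~ sum_k w_k exp(-x t_k),
# which turns the MP2 denominator into separable exponential factors that
# are absorbed into occupied/virtual pseudodensities per quadrature point.

#' Fit an exponential quadrature for 1/x
#'
#' Nonlinear least-squares fit (Levenberg-Marquardt on log parameters,
#' initialized from a geometric progression) of
#' `sum_k w_k exp(-x t_k) ~ 1/x` on `[x_min, x_max]`, minimizing relative
#' error on a log-spaced sample.  The fit is performed on the scaled
#' interval `[1, x_max/x_min]` and rescaled, so quality depends only on the
#' interval ratio.
#'
#' @param x_min,x_max interval bounds (energy gaps, Hartree), 0 < x_min <=
#'   x_max
#' @param K number of quadrature points (default 7)
#' @param n_check size of the dense log-spaced sample used to measure the
#'   stored maximum relative error (>= 1e4)
#' @return object of class `laplace_quadrature` with fields `omega`, `tau`,
#'   `K`, `x_min`, `x_max`, `max_rel_error`
#' @export
fit_laplace_quadrature <- function(x_min, x_max, K = 7L, n_check = 1e4) {
  stopifnot(x_min > 0, x_max >= x_min, K >= 1)
  R <- x_max / x_min
  if (R < 1 + 1e-12 && K == 1L) {
    # degenerate interval: one-point interpolation w e^{-a t} = 1/a
    q <- list(omega = exp(1) / x_min, tau = 1 / x_min, K = 1L,
              x_min = x_min, x_max = x_max, max_rel_error = 0)
    class(q) <- "laplace_quadrature"
    return(q)
  }
  # fit on [1, R]; warm-start chain over increasing point counts with a
  # best-of-candidates selection, so the measured error is non-increasing
  # in K by construction
  xdense <- exp(seq(log(1), log(max(R, 1 + 1e-9)),
                    length.out = max(n_check, 1e4)))
  dense_err <- function(w, t)
    max(abs(colSums(w * exp(-outer(t, xdense))) * xdense - 1))
  refine <- function(w0, t0) {
    k <- length(t0)
    xs <- exp(seq(log(1), log(max(R, 1 + 1e-9)),
                  length.out = max(80, 12 * k)))
    resid_fun <- function(par) {
      w <- exp(par[1:k]); t <- exp(par[k + 1:k])
      colSums(w * exp(-outer(t, xs))) * xs - 1
    }
    fit <- minpack.lm::nls.lm(c(log(w0), log(t0)), fn = resid_fun,
                              control = minpack.lm::nls.lm.control(
                                maxiter = 400, ftol = 1e-15, ptol = 1e-15))
    list(w = exp(fit$par[1:k]), t = exp(fit$par[k + 1:k]))
  }
  best <- NULL
  for (k in seq_len(K)) {
    t0 <- exp(seq(log(0.1 / R), log(3), length.out = k))
    w0 <- t0 * log(if (k > 1) (t0[2] / t0[1]) else exp(1))
    cands <- list(refine(w0, t0))
    if (!is.null(best)) {
      # previous solution padded with a negligible-weight extra exponent:
      # reproduces the (k-1)-point error exactly, and seeds the refinement
      tpad <- c(best$t, exp(mean(log(best$t))) * 1.37)
      wpad <- c(best$w, 1e-280)
      cands <- c(cands, list(list(w = wpad, t = tpad)), list(refine(wpad, tpad)))
    }
    errs <- vapply(cands, function(cc) dense_err(cc$w, cc$t), 0)
    best <- cands[[which.min(errs)]]
    best$err <- min(errs)
  }
  ord <- order(best$t)
  w <- best$w[ord]; t <- best$t[ord]
  err <- best$err
  q <- list(omega = w / x_min, tau = t / x_min, K = as.integer(K),
            x_min = x_min, x_max = x_max, max_rel_error = err)
  class(q) <- "laplace_quadrature"
  q
}

#' @export
print.laplace_quadrature <- function(x, ...) {
  cat(sprintf(
    "laplace_quadrature: K=%d on [%.4g, %.4g], max rel err %.3g\n",
    x$K, x$x_min, x$x_max, x$max_rel_error))
  invisible(x)
}

#' Evaluate the quadrature approximation of 1/x
#' @param quad a `laplace_quadrature`
#' @param x numeric vector
#' @return numeric vector of the same length
#' @export
laplace_eval <- function(quad, x)
  colSums(quad$omega * exp(-outer(quad$tau, x)))

# quadrature dump/load as plain-text key-value pairs (reproducibility)
#' @rdname fit_laplace_quadrature
#' @param quad a `laplace_quadrature`
#' @param path file path
#' @export
laplace_save <- function(quad, path) {
  writeLines(c(
    paste("K", quad$K), paste("x_min", quad$x_min),
    paste("x_max", quad$x_max), paste("max_rel_error", quad$max_rel_error),
    paste("omega", paste(sprintf("%.17g", quad$omega), collapse = " ")),
    paste("tau", paste(sprintf("%.17g", quad$tau), collapse = " "))), path)
}

#' @rdname fit_laplace_quadrature
#' @export
laplace_load <- function(path) {
  kv <- strsplit(readLines(path), " ")
  g <- function(key) {
    r <- kv[[which(vapply(kv, `[[`, "", 1) == key)]]
    as.numeric(r[-1])
  }
  q <- list(omega = g("omega"), tau = g("tau"), K = as.integer(g("K")),
            x_min = g("x_min"), x_max = g("x_max"),
            max_rel_error = g("max_rel_error"))
  class(q) <- "laplace_quadrature"
  q
}

# denominator spectrum bounds: per spin twice the smallest/largest
# occupied-virtual gap, merged over spins
laplace_interval <- function(scf) {
  lo <- Inf; hi <- -Inf
  for (sp in spins) {
    no <- scf$n_occ[[sp]]; eps <- scf$eps[[sp]]
    if (no == 0 || no == length(eps)) next
    occ <- eps[seq_len(no)]; virt <- eps[-seq_len(no)]
    lo <- min(lo, 2 * (min(virt) - max(occ)))
    hi <- max(hi, 2 * (max(virt) - min(occ)))
  }
  if (!is.finite(lo)) return(NULL)  # no occupied-virtual pairs at all
  c(lo, hi)
}

#' Laplace quadrature matched to an SCF spectrum
#'
#' @param scf an `scf_context`
#' @param K number of points
#' @return a `laplace_quadrature`, or NULL for systems without
#'   occupied-virtual pairs (e.g. a one-electron atom in a minimal basis)
#' @export
laplace_for_scf <- function(scf, K = 7L, pad = 0.005) {
  iv <- laplace_interval(scf)
  if (is.null(iv)) return(NULL)
  # slight padding so nearby spectra (finite-difference displacements)
  # remain inside the fitted interval
  fit_laplace_quadrature(iv[1] * (1 - pad), iv[2] * (1 + pad), K)
}

#' Pseudodensities at one Laplace point
#'
#' Occupied and virtual pseudodensities
#' `Pocc(k) = C_occ exp(+eps_occ tau_k) C_occ^T`,
#' `Pvirt(k) = C_virt exp(-eps_virt tau_k) C_virt^T` per spin.  Quadrature
#' weights are NOT folded in; contractions apply `omega_k` explicitly.
#'
#' @param scf an `scf_context`
#' @param quad a `laplace_quadrature` whose interval covers the denominator
#'   spectrum
#' @param kappa quadrature point index
#' @return list with per-spin matrices `Pocc`, `Pvirt`, plus `kappa`,
#'   `omega`, `tau`
#' @export
build_pseudodensities <- function(scf, quad, kappa) {
  stopifnot(kappa >= 1, kappa <= quad$K)
  iv <- laplace_interval(scf)
  if (!is.null(iv) && (iv[1] < quad$x_min * (1 - 1e-9) ||
                       iv[2] > quad$x_max * (1 + 1e-9)))
    stop(sprintf(
      "denominator spectrum [%.6g, %.6g] outside quadrature interval [%.6g, %.6g]",
      iv[1], iv[2], quad$x_min, quad$x_max))
  tau <- quad$tau[kappa]
  nb <- scf$n_bf
  out <- list(kappa = kappa, omega = quad$omega[kappa], tau = tau,
              Pocc = list(), Pvirt = list())
  for (sp in spins) {
    no <- scf$n_occ[[sp]]
    C <- scf$C[[sp]]; eps <- scf$eps[[sp]]
    if (no > 0) {
      Co <- C[, seq_len(no), drop = FALSE]
      out$Pocc[[sp]] <- Co %*% (exp(eps[seq_len(no)] * tau) * t(Co))
    } else out$Pocc[[sp]] <- matrix(0, nb, nb)
    if (no < length(eps)) {
      Cv <- C[, -seq_len(no), drop = FALSE]
      out$Pvirt[[sp]] <- Cv %*% (exp(-eps[-seq_len(no)] * tau) * t(Cv))
    } else out$Pvirt[[sp]] <- matrix(0, nb, nb)
  }
  out
}

#' Pivoted Cholesky decomposition with threshold stopping
#'
#' Factorizes a symmetric PSD matrix as `M ~ L L^T` with columns of `L`
#' ordered by pivot magnitude, stopping when the largest remaining diagonal
#' falls below `threshold` (absolute).  Small negative pivots (numerical
#' noise) are clamped to zero; pivots below `-10 * threshold` raise an
#' error.
#'
#' @param M symmetric matrix
#' @param threshold absolute stopping threshold
#' @param max_rank optional rank cap (used by grid selection)
#' @return matrix `L` (n x rank); attribute `pivots` holds the pivot order
#' @export
pivoted_cholesky <- function(M, threshold = 1e-8, max_rank = Inf) {
  n <- nrow(M)
  d <- diag(M)
  if (any(d < -10 * threshold))
    stop("matrix is not PSD: diagonal entry ", min(d))
  L <- matrix(0, n, n)
  piv <- integer(0)
  r <- 0L
  while (TRUE) {
    j <- which.max(d)
    dj <- d[j]
    if (dj <= threshold) break
    r <- r + 1L
    piv[r] <- j
    col <- M[, j]
    if (r > 1)
      col <- col - L[, seq_len(r - 1), drop = FALSE] %*% L[j, seq_len(r - 1)]
    L[, r] <- col / sqrt(dj)
    d <- d - L[, r]^2
    if (any(d < -10 * threshold))
      stop("negative pivot ", min(d), " below tolerance")
    d[d < 0] <- 0
    d[piv] <- 0
    if (r == n || r >= max_rank) break
  }
  out <- L[, seq_len(r), drop = FALSE]
  attr(out, "pivots") <- piv
  out
}

#' Cholesky pseudo-MO coefficients for one Laplace point
#'
#' @param pd pseudodensity pair from [build_pseudodensities()]
#' @param threshold pivoted-Cholesky stopping threshold
#' @return list with per-spin factors `Locc` (n_bf x r_occ) and `Lvirt`
#' @export
cholesky_mos <- function(pd, threshold = 1e-8) {
  out <- list(threshold = threshold, kappa = pd$kappa,
              Locc = list(), Lvirt = list())
  for (sp in spins) {
    out$Locc[[sp]] <- pivoted_cholesky(pd$Pocc[[sp]], threshold)
    out$Lvirt[[sp]] <- pivoted_cholesky(pd$Pvirt[[sp]], threshold)
  }
  out
}
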