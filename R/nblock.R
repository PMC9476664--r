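# Natural blocking: significance lists over index pairs, built from
# screening matrices, driving the screened exchange-like contractions.
# A pair (i, j) is significant iff |A_ij| > eps (strictly); lists are
# stored as sorted index vectors per left index, so batched contractions
# iterate deterministically in ascending order.

#' Build a significance list from a screening matrix
#'
#' @param A screening matrix; rows are the left index
#' @param eps threshold; a pair is kept iff `|A_ij| > eps` (strict), so
#'   `eps = 0` keeps all pairs with nonzero screen value -- to keep
#'   genuinely all pairs use `eps = -1`
#' @return object of class `sig_list` with fields `n_left`, `n_right`,
#'   `sets` (list of sorted integer vectors), `eps`, `n_pairs`
#' @export
build_list <- function(A, eps) {
  A <- as.matrix(A)
  sets <- lapply(seq_len(nrow(A)), function(i) which(abs(A[i, ]) > eps))
  structure(list(n_left = nrow(A), n_right = ncol(A), sets = sets,
                 eps = eps, n_pairs = sum(lengths(sets))),
            class = "sig_list")
}

# complete list (every pair significant)
full_list <- function(n_left, n_right) {
  structure(list(n_left = n_left, n_right = n_right,
                 sets = rep(list(seq_len(n_right)), n_left),
                 eps = -1, n_pairs = n_left * n_right),
            class = "sig_list")
}

#' @export
print.sig_list <- function(x, ...) {
  cat(sprintf("sig_list %d x %d: N_pairs = %d (fill %.1f%%), eps = %g\n",
              x$n_left, x$n_right, x$n_pairs,
              100 * x$n_pairs / max(1, x$n_left * x$n_right), x$eps))
  invisible(x)
}

#' Transpose a significance list
#'
#' `i` is significant for `j` in the result iff `j` was significant for
#' `i` in the input.
#'
#' @param L a `sig_list`
#' @return a `sig_list` with left/right dimensions swapped
#' @export
transpose_list <- function(L) {
  sets <- vector("list", L$n_right)
  for (i in seq_len(L$n_left))
    for (j in L$sets[[i]]) sets[[j]] <- c(sets[[j]], i)
  sets <- lapply(sets, function(s) if (is.null(s)) integer(0) else sort(s))
  structure(list(n_left = L$n_right, n_right = L$n_left, sets = sets,
                 eps = L$eps, n_pairs = sum(lengths(sets))),
            class = "sig_list")
}

#' Screening matrices from collocation factors
#'
#' `grid_orbital_screen` returns the element-magnitude screen `|X_iP|`
#' (orbital rows, grid columns), from which grid-orbital significance
#' lists are built.  `orbital_orbital_screen` returns
#' `M[i, a] = max_P |Xo_iP Xv_aP|`, the screen selecting orbital pairs
#' with non-negligible co-density on the grid.
#'
#' @param Xc transformed collocation matrix (orbitals x grid)
#' @return screening matrix
#' @export
grid_orbital_screen <- function(Xc) abs(Xc)

#' @rdname grid_orbital_screen
#' @param Xo,Xv occupied / virtual transformed collocation matrices
#'   (orbitals x grid, shared grid dimension)
#' @export
orbital_orbital_screen <- function(Xo, Xv) {
  stopifnot(ncol(Xo) == ncol(Xv))
  ao <- abs(Xo); av <- abs(Xv)
  M <- matrix(0, nrow(Xo), nrow(Xv))
  for (i in seq_len(nrow(Xo))) {
    sc <- av * rep(ao[i, ], each = nrow(Xv))
    M[i, ] <- if (ncol(sc)) apply(sc, 1, max) else 0
  }
  M
}

#' Compose two significance lists over a shared middle index
#'
#' Given lists `{a_j}` (left j, right a... stored as left-index j) and
#' `{a_i}`, returns the list over (j, i): `i` significant for `j` iff the
#' middle sets intersect.
#'
#' @param L_aj `sig_list` with left index j and right index a
#' @param L_ai `sig_list` with left index i and right index a
#' @return `sig_list` with left index j, right index i
#' @export
compose_lists <- function(L_aj, L_ai) {
  stopifnot(L_aj$n_right == L_ai$n_right)
  # boolean product over the middle dimension
  Bj <- matrix(FALSE, L_aj$n_left, L_aj$n_right)
  for (j in seq_len(L_aj$n_left)) Bj[j, L_aj$sets[[j]]] <- TRUE
  Bi <- matrix(FALSE, L_ai$n_left, L_ai$n_right)
  for (i in seq_len(L_ai$n_left)) Bi[i, L_ai$sets[[i]]] <- TRUE
  C <- (Bj + 0) %*% t(Bi + 0)
  sets <- lapply(seq_len(nrow(C)), function(j) which(C[j, ] > 0))
  structure(list(n_left = L_aj$n_left, n_right = L_ai$n_left, sets = sets,
                 eps = NA_real_, n_pairs = sum(lengths(sets))),
            class = "sig_list")
}

#' Natural-blocking threshold configuration
#'
#' Thresholds for the three list families of the screened exchange
#' contraction: `eps_Sj` (grid-occupied pairs, from the occupied
#' collocation screen), `eps_bR` (grid-virtual pairs), `eps_bj`
#' (virtual-occupied pairs, coupled in real space over grid points).
#'
#' @param eps_Sj,eps_bR,eps_bj non-negative thresholds; 0 disables
#'   screening (keeps all nonzero screen entries); use exact = TRUE for
#'   fully unscreened oracle runs
#' @param exact if TRUE all lists are complete regardless of thresholds
#' @return list of class `nb_config`
#' @export
nb_config <- function(eps_Sj = 1e-3, eps_bR = 1e-2, eps_bj = 1e-2,
                      exact = FALSE) {
  stopifnot(eps_Sj >= 0, eps_bR >= 0, eps_bj >= 0)
  structure(list(eps_Sj = eps_Sj, eps_bR = eps_bR, eps_bj = eps_bj,
                 exact = exact), class = "nb_config")
}

# build the {S_j} and {R_j} lists for the exchange contraction of one spin
nb_exchange_lists <- function(Xo, Xv, nb) {
  n_occ <- nrow(Xo); ng <- ncol(Xo)
  if (isTRUE(nb$exact) || n_occ == 0) {
    return(list(Sj = full_list(max(n_occ, 0), ng),
                Rj = full_list(max(n_occ, 0), ng),
                n_pairs_Sj = n_occ * ng, n_pairs_Rj = n_occ * ng))
  }
  Sj <- build_list(grid_orbital_screen(Xo), nb$eps_Sj)
  bR <- build_list(t(grid_orbital_screen(Xv)), nb$eps_bR)   # left R, right b
  bj <- build_list(orbital_orbital_screen(Xo, Xv), nb$eps_bj) # left j, right b
  Rj <- compose_lists(bj, bR)                               # left j, right R
  list(Sj = Sj, Rj = Rj, n_pairs_Sj = Sj$n_pairs, n_pairs_Rj = Rj$n_pairs)
}
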