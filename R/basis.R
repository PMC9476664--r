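# Gaussian basis sets.
#
# The package ships a minimal set ("sto-3g", reconstructed from the standard
# three-Gaussian least-squares fit to Slater functions with the usual
# per-element zeta scaling) and a package-defined split-valence variant
# ("dz") obtained by decontracting the loosest valence primitive.  Auxiliary
# (density-fitting) sets are generated on the fly as atom-centred
# even-tempered expansions ("autoaux").

# Three-term Gaussian fits of normalized 1s and 2s/2p Slater functions
# (zeta = 1); exponents scale as zeta^2.
.sto3g_fit <- list(
  s1 = list(exps = c(2.227660584, 0.405771156, 0.109818),
            coefs = c(0.154328967, 0.535328142, 0.444634542)),
  s2 = list(exps = c(0.994203, 0.231031, 0.0751386),
            coefs = c(-0.099967230, 0.399512826, 0.700115469)),
  p2 = list(exps = c(0.994203, 0.231031, 0.0751386),
            coefs = c(0.155916275, 0.607683719, 0.391957393))
)

# Slater exponents used by the minimal basis (1s; 2s/2p where applicable)
.sto3g_zeta <- list(
  H = c(1.24), He = c(1.69),
  B = c(4.68, 1.45), C = c(5.67, 1.72), N = c(6.67, 1.95),
  O = c(7.66, 2.25), F = c(8.65, 2.55)
)

# shells for one atom: list of list(l, exps, coefs) (no center yet)
.atom_shells <- function(symbol, basis) {
  z <- .sto3g_zeta[[symbol]]
  if (is.null(z)) stop("basis data unavailable for element '", symbol, "'")
  sh <- list()
  f <- .sto3g_fit
  add <- function(l, exps, coefs) sh[[length(sh) + 1]] <<-
    list(l = l, exps = exps, coefs = coefs)
  if (basis == "sto-3g") {
    add(0L, f$s1$exps * z[1]^2, f$s1$coefs)
    if (length(z) > 1) {
      add(0L, f$s2$exps * z[2]^2, f$s2$coefs)
      add(1L, f$p2$exps * z[2]^2, f$p2$coefs)
    }
  } else if (basis == "dz") {
    # split-valence: keep the core contraction, split the valence shell into
    # a two-primitive contraction plus the free loosest primitive
    if (length(z) == 1) {
      e <- f$s1$exps * z[1]^2; c1 <- f$s1$coefs
      add(0L, e[1:2], c1[1:2]); add(0L, e[3], 1)
    } else {
      add(0L, f$s1$exps * z[1]^2, f$s1$coefs)
      es <- f$s2$exps * z[2]^2
      add(0L, es[1:2], f$s2$coefs[1:2]); add(0L, es[3], 1)
      add(1L, es[1:2], f$p2$coefs[1:2]); add(1L, es[3], 1)
    }
  } else stop("unknown basis '", basis, "' (available: sto-3g, dz)")
  sh
}

#' Build the shell list of a molecule
#'
#' @param mol a `molecule`
#' @param basis basis-set name ("sto-3g" or "dz")
#' @return list of shells `list(l, center, exps, coefs)` with centres in bohr
#' @export
basis_shells <- function(mol, basis = "sto-3g") {
  xyz <- mol_coords_bohr(mol)
  out <- list()
  for (i in seq_along(mol$symbols)) {
    for (sh in .atom_shells(mol$symbols[i], basis)) {
      sh$center <- xyz[i, ]
      out[[length(out) + 1]] <- sh
    }
  }
  out
}

#' Even-tempered auxiliary basis
#'
#' Generates an atom-centred even-tempered density-fitting basis from the
#' orbital basis: for each auxiliary angular momentum l (0 .. l_max + 1) the
#' exponent range is spanned by sums of primitive-exponent pairs whose
#' angular momenta can couple to l, covered by a geometric progression with
#' ratio `beta`.
#'
#' @param mol a `molecule`
#' @param basis orbital basis name the set is matched to
#' @param beta even-tempered ratio (> 1); smaller is denser/more accurate
#' @return shell list in the same format as [basis_shells()]
#' @export
autoaux_shells <- function(mol, basis = "sto-3g", beta = 2.3) {
  xyz <- mol_coords_bohr(mol)
  out <- list()
  for (i in seq_along(mol$symbols)) {
    ash <- .atom_shells(mol$symbols[i], basis)
    ls <- vapply(ash, `[[`, 0L, "l")
    lmax <- max(ls)
    for (laux in 0:(lmax + 1L)) {
      prs <- list()
      for (a in seq_along(ash)) for (b in seq_along(ash))
        if (ls[a] + ls[b] >= laux)
          prs[[length(prs) + 1]] <- outer(ash[[a]]$exps, ash[[b]]$exps, "+")
      if (!length(prs))  # fall back to all pairs (e.g. p on hydrogen)
        for (a in seq_along(ash)) for (b in seq_along(ash))
          prs[[length(prs) + 1]] <- outer(ash[[a]]$exps, ash[[b]]$exps, "+")
      rng <- range(unlist(prs))
      n <- max(1L, ceiling(log(rng[2] / rng[1]) / log(beta)))
      exps <- rng[1] * beta^(0:n)
      for (e in exps)
        out[[length(out) + 1]] <- list(l = laux, center = xyz[i, ],
                                       exps = e, coefs = 1)
    }
  }
  out
}

n_basis_functions <- function(shells)
  sum(vapply(shells, function(s) ((s$l + 1L) * (s$l + 2L)) %/% 2L, 0L))

# basis-function labels "atom index: element l-component"
basis_labels <- function(mol, shells) {
  xyz <- mol_coords_bohr(mol)
  lab <- character(0)
  lnames <- c("s", "p", "d", "f", "g", "h")
  for (s in shells) {
    at <- which(apply(xyz, 1, function(r) all(abs(r - s$center) < 1e-10)))[1]
    nc <- (s$l + 1) * (s$l + 2) / 2
    lab <- c(lab, paste0(mol$symbols[at], at, "-", lnames[s$l + 1],
                         seq_len(nc)))
  }
  lab
}
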