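#' Molecular structure
#'
#' Creates a molecule object from element symbols and Cartesian coordinates
#' in Angstrom.  The electron count must be consistent with the charge and
#' the spin multiplicity (number of unpaired electrons = multiplicity - 1).
#'
#' @param symbols character vector of element symbols
#' @param coords numeric matrix (n_atoms x 3) of Cartesian positions, Angstrom
#' @param charge integer total charge
#' @param multiplicity integer spin multiplicity (2S + 1), >= 1
#' @return an object of class `molecule`
#' @export
molecule <- function(symbols, coords, charge = 0L, multiplicity = 1L) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  stopifnot(length(symbols) == nrow(coords), multiplicity >= 1)
  Z <- .element_numbers[symbols]
  if (anyNA(Z)) stop("unknown element symbol(s): ",
                     paste(symbols[is.na(Z)], collapse = ", "))
  nelec <- sum(Z) - charge
  if (nelec < 1) stop("no electrons")
  nunpaired <- multiplicity - 1L
  if (nelec < nunpaired || (nelec - nunpaired) %% 2 != 0)
    stop("electron count ", nelec, " inconsistent with multiplicity ",
         multiplicity)
  structure(list(symbols = as.character(symbols), coords = coords,
                 charge = as.integer(charge),
                 multiplicity = as.integer(multiplicity),
                 Z = unname(Z), n_electrons = as.integer(nelec),
                 n_alpha = as.integer((nelec + nunpaired) %/% 2),
                 n_beta = as.integer((nelec - nunpaired) %/% 2)),
            class = "molecule")
}

#' Read a molecule from an XYZ file
#'
#' Standard XYZ layout: atom count, comment line, then `element x y z` rows
#' in Angstrom.
#'
#' @param path file path
#' @inheritParams molecule
#' @return a `molecule`
#' @export
read_xyz <- function(path, charge = 0L, multiplicity = 1L) {
  ln <- readLines(path)
  n <- as.integer(trimws(ln[1]))
  rows <- strsplit(trimws(ln[3:(2 + n)]), "\\s+")
  sym <- vapply(rows, `[[`, "", 1)
  xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
  molecule(sym, xyz, charge, multiplicity)
}

#' Write a molecule to an XYZ file
#' @param mol a `molecule`
#' @param path output path
#' @param comment comment line
#' @export
write_xyz <- function(mol, path, comment = "") {
  co <- sprintf("%-3s %18.10f %18.10f %18.10f", mol$symbols,
                mol$coords[, 1], mol$coords[, 2], mol$coords[, 3])
  writeLines(c(length(mol$symbols), comment, co), path)
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("molecule: %d atoms, charge %d, multiplicity %d\n",
              length(x$symbols), x$charge, x$multiplicity))
  invisible(x)
}

# coordinates in bohr
mol_coords_bohr <- function(mol) mol$coords * .const$bohr_per_angstrom

nuclear_repulsion <- function(mol) {
  xyz <- mol_coords_bohr(mol)
  n <- nrow(xyz)
  e <- 0
  if (n > 1)
    for (i in 1:(n - 1))
      for (j in (i + 1):n)
        e <- e + mol$Z[i] * mol$Z[j] / sqrt(sum((xyz[i, ] - xyz[j, ])^2))
  e
}
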