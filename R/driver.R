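# End-to-end driver: configuration, the full HFCC pipeline, result tables,
# and the independent finite-difference derivative oracle.

#' Run configuration
#'
#' Collects every tunable of the pipeline with its default: basis set,
#' number of Laplace points (7), attenuated-metric strength (0.1), THC
#' grid ratio (3 x N_aux), natural-blocking thresholds
#' (1e-3 / 1e-2 / 1e-2), CPSCF convergence (1e-4), and SCF thresholds
#' (1e-8 energy, 1e-7 commutator).
#'
#' @param basis,aux_basis basis names
#' @param n_laplace Laplace points (1..16)
#' @param omega attenuation strength of the fitting metric
#' @param grid_ratio THC grid size relative to the auxiliary basis
#' @param eps_Sj,eps_bR,eps_bj natural-blocking thresholds
#' @param cpscf_conv CPSCF residual threshold
#' @param scf_energy,scf_commutator SCF convergence thresholds
#' @param method "thc" (fast path) or "dense" (oracle path)
#' @param eri_source "ri" or "dense" projection in the THC fit
#' @param metric "attenuated" or "coulomb"
#' @param nuclei "all" or integer vector of nucleus indices
#' @param seed seed for any randomized test data
#' @return list of class `run_config`
#' @export
run_config <- function(basis = "sto-3g", aux_basis = "autoaux",
                       n_laplace = 7L, omega = 0.1, grid_ratio = 3.0,
                       eps_Sj = 1e-3, eps_bR = 1e-2, eps_bj = 1e-2,
                       cpscf_conv = 1e-4, scf_energy = 1e-8,
                       scf_commutator = 1e-7, method = "thc",
                       eri_source = "ri", metric = "attenuated",
                       nuclei = "all", seed = 1L) {
  stopifnot(n_laplace >= 1, n_laplace <= 16, omega > 0, grid_ratio > 0,
            cpscf_conv > 0, scf_energy > 0, scf_commutator > 0)
  structure(list(basis = basis, aux_basis = aux_basis,
                 n_laplace = as.integer(n_laplace), omega = omega,
                 grid_ratio = grid_ratio, eps_Sj = eps_Sj, eps_bR = eps_bR,
                 eps_bj = eps_bj, cpscf_conv = cpscf_conv,
                 scf_energy = scf_energy, scf_commutator = scf_commutator,
                 method = method, eri_source = eri_source, metric = metric,
                 nuclei = nuclei, seed = as.integer(seed)),
            class = "run_config")
}

#' Serialize / parse a run configuration (plain key: value lines)
#' @param config a `run_config`
#' @param path file path
#' @export
config_save <- function(config, path) {
  vals <- unclass(config)
  writeLines(vapply(names(vals), function(k)
    paste0(k, ": ", paste(vals[[k]], collapse = ",")), ""), path)
}

#' @rdname config_save
#' @export
config_load <- function(path) {
  kv <- strsplit(readLines(path), ": ", fixed = TRUE)
  vals <- setNames(lapply(kv, `[[`, 2), vapply(kv, `[[`, "", 1))
  num <- function(x) as.numeric(x)
  run_config(basis = vals$basis, aux_basis = vals$aux_basis,
             n_laplace = num(vals$n_laplace), omega = num(vals$omega),
             grid_ratio = num(vals$grid_ratio), eps_Sj = num(vals$eps_Sj),
             eps_bR = num(vals$eps_bR), eps_bj = num(vals$eps_bj),
             cpscf_conv = num(vals$cpscf_conv),
             scf_energy = num(vals$scf_energy),
             scf_commutator = num(vals$scf_commutator),
             method = vals$method, eri_source = vals$eri_source,
             metric = vals$metric,
             nuclei = if (identical(vals$nuclei, "all")) "all" else
               as.integer(strsplit(vals$nuclei, ",")[[1]]),
             seed = num(vals$seed))
}

#' Full HFCC pipeline for one molecule
#'
#' SCF, Laplace quadrature, R-matrix formation (THC fast path or dense
#' oracle path), Z-vector response, and per-nucleus Fermi-contact traces.
#'
#' @param mol a [molecule()] or path to an XYZ file
#' @param config a [run_config()]
#' @param charge,multiplicity used when `mol` is an XYZ path
#' @param verbose print a progress line per stage
#' @return list of class `hfcc_run`: `results` (data.frame, one row per
#'   nucleus), `diagnostics`, and the intermediate objects
#' @export
run_hfcc <- function(mol, config = run_config(), charge = 0L,
                     multiplicity = 1L, verbose = FALSE) {
  if (is.character(mol)) mol <- read_xyz(mol, charge, multiplicity)
  say <- function(...) if (verbose) message(sprintf(...))
  say("[scf] %s/%s", config$basis, config$aux_basis)
  scf <- build_scf_context(mol, config$basis, config$aux_basis,
                           conv = list(energy = config$scf_energy,
                                       commutator = config$scf_commutator))
  quad <- laplace_for_scf(scf, config$n_laplace)
  say("[laplace] K=%d fit error %.2e", config$n_laplace,
      if (is.null(quad)) 0 else quad$max_rel_error)
  diag_info <- list(E_SCF = scf$E_SCF,
                    scf_iterations = scf$scf_iterations,
                    quadrature_error = if (is.null(quad)) 0 else
                      quad$max_rel_error)
  thc <- NULL
  if (is.null(quad)) {
    Rlist <- list()
  } else if (config$method == "dense") {
    Rlist <- lapply(seq_len(quad$K), function(k)
      r_dense_oracle(scf, build_pseudodensities(scf, quad, k)))
  } else {
    thc <- build_thc(scf, target_ratio = config$grid_ratio,
                     metric = config$metric, omega = config$omega,
                     eri_source = config$eri_source)
    say("[thc] %d grid points, gram cond %.2e", thc$grid$n_grid,
        thc$gram_condition)
    diag_info$thc <- list(n_grid = thc$grid$n_grid,
                          gram_condition = thc$gram_condition,
                          clamp = thc$clamp_report,
                          collocation_sparsity = thc$collocation_sparsity)
    nb <- nb_config(config$eps_Sj, config$eps_bR, config$eps_bj)
    Rlist <- build_R(scf, thc, quad, nb)
    diag_info$per_kappa <- do.call(rbind, lapply(Rlist, function(Rk)
      data.frame(kappa = Rk$kappa, elapsed_s = Rk$elapsed_s,
                 n_pairs_Sj_alpha = Rk$alpha$lists$n_pairs_Sj,
                 n_pairs_Rj_alpha = Rk$alpha$lists$n_pairs_Rj,
                 n_pairs_Sj_beta = Rk$beta$lists$n_pairs_Sj,
                 n_pairs_Rj_beta = Rk$beta$lists$n_pairs_Rj)))
  }
  say("[response] relaxed density + Z-vector")
  relaxed <- mp2_relaxed_density(scf, quad, Rlist,
                                 cpscf_conv = config$cpscf_conv)
  diag_info$cpscf <- relaxed$cpscf
  diag_info$y_residual <- relaxed$y_residual
  nuclei <- if (identical(config$nuclei, "all"))
    seq_along(mol$symbols) else config$nuclei
  rows <- lapply(nuclei, function(k) {
    r <- compute_hfcc(scf, relaxed, k)
    data.frame(nucleus = k, element = r$element, isotope = r$isotope,
               A_iso_SCF = r$A_iso_SCF, A_iso_MP2 = r$A_iso_MP2,
               A_iso_total = r$A_iso_total)
  })
  structure(list(results = do.call(rbind, rows), diagnostics = diag_info,
                 scf = scf, quad = quad, thc = thc, Rlist = Rlist,
                 relaxed = relaxed, config = config),
            class = "hfcc_run")
}

#' @export
print.hfcc_run <- function(x, ...) {
  cat("Isotropic hyperfine coupling constants (MHz)\n")
  df <- x$results
  df[, 4:6] <- round(df[, 4:6], 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write an HFCC result table to CSV
#' @param run an `hfcc_run`
#' @param path output path
#' @export
write_hfcc_csv <- function(run, path) {
  write.csv(run$results, path, row.names = FALSE)
}

#' Finite-difference HFCC oracle
#'
#' Independent derivative reference: adds the spin-dependent scaled
#' Fermi-contact operator to the core Hamiltonian (`+lambda` for alpha,
#' `-lambda` for beta), re-solves the SCF tightly, evaluates the dense
#' Laplace-MP2 energy with the frozen unperturbed quadrature, and forms
#' the central difference, converted to MHz with the same constants as
#' [compute_hfcc()].
#'
#' @param mol a [molecule()]
#' @param k nucleus index
#' @param lambda perturbation strength (plateau region about 1e-4..1e-6)
#' @param config a [run_config()] (basis and Laplace settings are used)
#' @param quad optional frozen quadrature (default: fit on unperturbed
#'   spectrum)
#' @return list with `A_total`, `A_SCF`, `A_MP2` in MHz
#' @export
fd_hfcc_oracle <- function(mol, k, lambda = 1e-5, config = run_config(),
                           quad = NULL) {
  conv <- list(energy = 1e-12, commutator = 1e-10)
  scf0 <- build_scf_context(mol, config$basis, config$aux_basis, conv = conv)
  if (is.null(quad)) quad <- laplace_for_scf(scf0, config$n_laplace)
  fc <- fermi_contact_integrals(scf0, k)
  pref <- .fc_prefactor_mhz * isotope_g_factor(mol$symbols[k])$g
  energies <- function(l) {
    cx <- build_scf_context(mol, config$basis, config$aux_basis, conv = conv,
                            h_alpha = l * fc$H_FC, h_beta = -l * fc$H_FC)
    c(scf = cx$E_SCF, mp2 = mp2_energy_laplace_dense(cx, quad))
  }
  ep <- energies(lambda); em <- energies(-lambda)
  d <- (ep - em) / (2 * lambda)
  list(A_SCF = pref * d[["scf"]], A_MP2 = pref * d[["mp2"]],
       A_total = pref * sum(d), lambda = lambda)
}
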