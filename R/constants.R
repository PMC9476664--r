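#' @useDynLib thcmp2, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif median setNames
#' @importFrom utils write.csv head tail
NULL

# CODATA 2018 values
.const <- list(
  bohr_per_angstrom = 1.8897259886,
  mu0      = 4e-7 * pi,          # vacuum permeability, N A^-2
  g_e      = 2.00231930436256,   # free-electron g factor (magnitude)
  mu_B     = 9.2740100783e-24,   # Bohr magneton, J T^-1
  mu_N     = 5.0507837461e-27,   # nuclear magneton, J T^-1
  planck_h = 6.62607015e-34,     # J s
  a0_m     = 0.529177210903e-10  # Bohr radius, m
)

# Fermi-contact prefactor: A_iso[MHz] = .fc_prefactor_mhz * g_N * rho_spin(R_k)
# with the spin density in atomic units (a0^-3).
.fc_prefactor_mhz <- with(.const,
  (2 / 3) * mu0 * g_e * mu_B * mu_N / (planck_h * a0_m^3)) * 1e-6

# Nuclear g factors of the most abundant magnetic isotope per element
.g_factors <- list(
  H = list(isotope = "1H",  g = 5.58569468),
  B = list(isotope = "11B", g = 1.7924326),
  C = list(isotope = "13C", g = 1.40482057),
  N = list(isotope = "14N", g = 0.40376100),
  O = list(isotope = "17O", g = -0.757516),
  F = list(isotope = "19F", g = 5.257736),
  P = list(isotope = "31P", g = 2.26320)
)

.element_numbers <- c(H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7,
                      O = 8, F = 9, Ne = 10, P = 15, S = 16, Cl = 17)

#' Nuclear g-factor lookup
#'
#' @param symbol element symbol (e.g. "H", "C")
#' @return list with `isotope` and `g`
#' @export
isotope_g_factor <- function(symbol) {
  gf <- .g_factors[[symbol]]
  if (is.null(gf))
    stop("no nuclear g-factor tabulated for element '", symbol,
         "'; available: ", paste(names(.g_factors), collapse = ", "))
  gf
}
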