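# Fixture molecules: small radicals (and closed-shell controls) with
# standard experimental/idealized geometries, used throughout the test and
# validation battery.  The n-propyl radical is the n = 3 member of the
# linear alkyl radical series at desk scale.

#' Fixture molecules
#'
#' Returns the package's built-in validation set: the hydrogen atom, the
#' hydroxyl radical (r = 0.970 A), planar methyl (C-H 1.079 A), the amino
#' radical NH2, water as a closed-shell control, the hydrogen molecule, and
#' the n-propyl radical.
#'
#' @param tags optional character vector to filter by size-class tag
#'   ("atom", "small", "medium")
#' @return named list of entries `list(name, molecule, tags)`
#' @export
fixtures <- function(tags = NULL) {
  deg <- pi / 180
  fx <- list(
    H = list(name = "H", tags = c("atom", "one-electron"),
             molecule = molecule("H", matrix(0, 1, 3), 0L, 2L)),
    H2 = list(name = "H2", tags = c("small", "closed-shell"),
              molecule = molecule(c("H", "H"),
                                  rbind(c(0, 0, 0), c(0, 0, 0.74)), 0L, 1L)),
    OH = list(name = "OH", tags = "small",
              molecule = molecule(c("O", "H"),
                                  rbind(c(0, 0, 0), c(0, 0, 0.970)), 0L, 2L)),
    H2O = list(name = "H2O", tags = c("small", "closed-shell"),
               molecule = {
                 a <- 104.52 * deg; r <- 0.9572
                 molecule(c("O", "H", "H"),
                          rbind(c(0, 0, 0),
                                c(r * sin(a / 2), 0, r * cos(a / 2)),
                                c(-r * sin(a / 2), 0, r * cos(a / 2))),
                          0L, 1L)
               }),
    NH2 = list(name = "NH2", tags = "small",
               molecule = {
                 a <- 103.3 * deg; r <- 1.024
                 molecule(c("N", "H", "H"),
                          rbind(c(0, 0, 0),
                                c(r * sin(a / 2), 0, r * cos(a / 2)),
                                c(-r * sin(a / 2), 0, r * cos(a / 2))),
                          0L, 2L)
               }),
    CH3 = list(name = "CH3", tags = "small",
               molecule = {
                 r <- 1.079  # planar D3h
                 molecule(c("C", "H", "H", "H"),
                          rbind(c(0, 0, 0),
                                c(r, 0, 0),
                                c(-r / 2, r * sqrt(3) / 2, 0),
                                c(-r / 2, -r * sqrt(3) / 2, 0)),
                          0L, 2L)
               }),
    C3H7 = list(name = "C3H7", tags = "medium",
                molecule = molecule(
                  c("C", "C", "C", "H", "H", "H", "H", "H", "H", "H"),
                  rbind(c(0.0000, 0.0000, 0.0000),
                        c(1.2460, 0.0000, 0.8810),
                        c(2.4919, 0.0000, 0.0000),
                        c(3.3852, 0.0000, 0.6316),
                        c(2.4919, 0.8933, -0.6316),
                        c(2.4919, -0.8933, -0.6316),
                        c(1.2460, 0.8933, 1.5126),
                        c(1.2460, -0.8933, 1.5126),
                        c(0.0991, 0.0000, -1.0754),
                        c(-0.9809, 0.0000, 0.4519)),
                  0L, 2L))
  )
  if (!is.null(tags))
    fx <- Filter(function(f) any(f$tags %in% tags), fx)
  fx
}
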