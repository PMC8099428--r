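#' Physical constants used throughout the package
#'
#' CODATA 2018 exact values, fixed in one place so every thermodynamic
#' conversion in the package agrees. Temperatures default to 300 K, the
#' temperature at which the channel models this package targets are simulated.
#'
#' @return A named list with elements `kB` (Boltzmann constant, J/K),
#'   `h` (Planck constant, J.s), `R` (molar gas constant, J/mol/K),
#'   `NA_avogadro` (1/mol) and `T_default` (K).
#' @examples
#' physical_constants()$kB
#' @export
physical_constants <- function() {
  list(
    kB          = 1.380649e-23,
    h           = 6.62607015e-34,
    R           = 8.31446261815324,
    NA_avogadro = 6.02214076e23,
    T_default   = 300
  )
}

# attempt frequency kB*T/h in 1/s
kbt_over_h <- function(temperature) {
  pc <- physical_constants()
  pc$kB * temperature / pc$h
}
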