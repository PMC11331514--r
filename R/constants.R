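# Physical constants (CODATA 2018) and unit conversions. All lengths in the
# package are Angstrom, energies k_B*T, charges e0.

.codata <- list(
  e0   = 1.602176634e-19,   # elementary charge, C
  eps0 = 8.8541878128e-12,  # vacuum permittivity, F/m
  kB   = 1.380649e-23,      # Boltzmann constant, J/K
  NAv  = 6.02214076e23      # Avogadro constant, 1/mol
)

# 1 mol/L expressed as ions per cubic Angstrom
.MOLAR_TO_A3 <- .codata$NAv / 1e27

#' Convert molar concentration to number density
#'
#' @param c concentration in mol/L.
#' @return number density in ions per cubic Angstrom
#'   (1 M = 6.02214e-4 ions/A^3).
#' @export
molar_to_density <- function(c) c * .MOLAR_TO_A3

#' Convert number density to molar concentration
#'
#' @param n number density in ions per cubic Angstrom.
#' @return concentration in mol/L.
#' @export
density_to_molar <- function(n) n / .MOLAR_TO_A3
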