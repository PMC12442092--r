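#' Physical constants
#'
#' CODATA-2018 values used throughout the package, collected in one place so
#' every thermochemical and kinetic quantity is derived from the same set.
#'
#' \describe{
#'   \item{R_kcal}{molar gas constant, kcal mol^-1 K^-1}
#'   \item{R_Latm}{molar gas constant, L atm mol^-1 K^-1}
#'   \item{kB}{Boltzmann constant, J K^-1}
#'   \item{h}{Planck constant, J s}
#'   \item{hartree_kcal}{1 hartree in kcal mol^-1}
#'   \item{hartree_eV}{1 hartree in eV}
#' }
#'
#' @format A named list of length 6.
#' @export
#' @examples
#' phys_const$R_kcal
phys_const <- list(
  R_kcal       = 8.31446261815324 / 4184,       # 1.987204e-3 kcal/(mol K)
  R_Latm       = 8.31446261815324 / 101.325,    # 0.08205737 L atm/(mol K)
  kB           = 1.380649e-23,
  h            = 6.62607015e-34,
  hartree_kcal = 627.5095,
  hartree_eV   = 27.2114
)

# Eyring prefactor kB*T/h in s^-1
.eyring_prefactor <- function(T) phys_const$kB * T / phys_const$h
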