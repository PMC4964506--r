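## Unit conventions used throughout the package:
##   length A, time ns, charge e, dipole e*A (Debye on input), energy eV,
##   field V/A, diffusivity A^2/ps, D_n 1/ns, p_f cm^3/s.
## All conversions out of this system live in osmotic_permeability().

#' Physical constants and unit conversions
#'
#' Centralised constants: `debye_eA` (1 Debye in e*Angstrom), `kB_eV`
#' (Boltzmann constant in eV/K), `temperature_K` (thermostat set point used
#' for every Boltzmann factor), `kT_eV` (their product), and `v_w_cm3`
#' (default average volume of one water molecule, used by
#' [osmotic_permeability()]).
#'
#' @return Named list of constants.
#' @examples
#' aq_constants()$kT_eV
#' @export
aq_constants <- function() {
  kB <- 8.617333262e-5
  Tk <- 298
  list(
    debye_eA      = 0.2081943,   # 1 D = 0.2081943 e*A
    kB_eV         = kB,
    temperature_K = Tk,
    kT_eV         = kB * Tk,
    v_w_cm3       = 3.0e-23      # bulk water molecular volume (18 g/mol / 0.997 g/cm^3 / N_A)
  )
}

#' @keywords internal
.kT <- function() aq_constants()$kT_eV

#' @keywords internal
.debye <- function() aq_constants()$debye_eA
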