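#' Physical constants for electrophysiology
#'
#' Faraday constant, molar gas constant and the default assay temperature
#' (37 degrees C).  Only the temperature is meant to be overridden.
#'
#' @param temperature_K absolute temperature in kelvin.
#' @return list with `F_C_mol`, `R_J_mol_K` and `T_K`.
#' @examples
#' physical_constants()$T_K        # 310.15
#' @export
physical_constants <- function(temperature_K = 310.15) {
  stopifnot(is.numeric(temperature_K), temperature_K > 0)
  list(F_C_mol = 96485, R_J_mol_K = 8.314, T_K = temperature_K)
}

# RT/F in millivolts at temperature T (thermal voltage).
rt_over_f_mV <- function(temperature_K = 310.15) {
  k <- physical_constants(temperature_K)
  1000 * k$R_J_mol_K * k$T_K / k$F_C_mol
}
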