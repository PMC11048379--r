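# Physical constants used throughout. Energies are handled internally in
# J/mol and converted to kJ/mol only at the reporting surface.

#' Physical constants for ion energetics
#'
#' Monoisotopic atomic masses (Da), the proton mass used for charging,
#' the elementary charge, the Boltzmann constant and the molar gas constant.
#' The gas constant defaults to 8.314 J/(mol K), the value conventionally
#' used in gas-phase dissociation energetics tables.
#'
#' @format A named list.
#' @export
cid_constants <- list(
  proton_mass   = 1.00727646,    # Da, bare proton (protonated pseudo-molecular ions)
  elementary_charge = 1.602176634e-19,  # C
  boltzmann     = 1.380649e-23,  # J/K
  gas_constant  = 8.314          # J/(mol K)
)

# IUPAC monoisotopic atomic masses of the most abundant isotopes.
.monoiso_masses <- c(
  H  = 1.0078250319,
  C  = 12.0,
  N  = 14.0030740052,
  O  = 15.9949146221,
  S  = 31.97207069,
  P  = 30.97376151,
  Se = 79.9165218,
  Na = 22.98976928,
  K  = 38.9637064864,
  Fe = 55.9349375,
  Zn = 63.9291422
)
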