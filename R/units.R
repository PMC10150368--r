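# Unit system: energies in eV, lengths in Angstrom, time in fs, mass in amu.

#' Physical constants used by polyenedyn
#'
#' `hbar_ev_fs` is the reduced Planck constant in eV fs; `amu_ev_fs2_A2`
#' converts atomic mass units to the internal mass unit eV fs^2 / A^2.
#'
#' @format Named numeric vector.
#' @export
pd_constants <- c(
  hbar_ev_fs    = 0.6582119569,
  amu_ev_fs2_A2 = 103.642696
)

.hbar <- function() pd_constants[["hbar_ev_fs"]]
.mass_internal <- function(m_amu) m_amu * pd_constants[["amu_ev_fs2_A2"]]
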