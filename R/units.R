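#' @title Physical constants and unit conversions
#' @description Internal unit conventions: geometry in Angstrom, angles in
#'   degrees at the user surface (radians internally where noted), energies in
#'   kcal/mol at the reporting surface. GROMACS-facing fields (topologies, MDP
#'   files) use the GROMACS native units: nm and kJ/mol.
#' @name septop-units
#' @keywords internal
NULL

# gas constant, kcal mol-1 K-1
.R_KCAL <- 1.98720425864083e-3

# kJ per kcal
.KJ_PER_KCAL <- 4.184

# standard-state volume (1 M), Angstrom^3 per molecule
.V_STANDARD <- 1660

#' Thermal energy RT in kcal/mol
#'
#' @param temperature Temperature in Kelvin.
#' @return RT in kcal/mol.
#' @examples
#' rt_kcal(298.15)
#' @export
rt_kcal <- function(temperature) {
  stopifnot(is.numeric(temperature), temperature > 0)
  .R_KCAL * temperature
}

#' Convert kcal/mol to kJ/mol and back
#'
#' @param x Energy value(s).
#' @return Converted value(s).
#' @export
kcal_to_kj <- function(x) x * .KJ_PER_KCAL

#' @rdname kcal_to_kj
#' @export
kj_to_kcal <- function(x) x / .KJ_PER_KCAL
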