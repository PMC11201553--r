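#' Physical constants used for unit conversion
#'
#' Conversion factors between atomic units and the kcal/mol + Angstrom
#' unit system the package works in, plus the gas constant used by
#' [ki_to_energy()]. CODATA values.
#'
#' @format A named list with components
#'   `hartree_to_kcalmol` (627.5094740631),
#'   `bohr_to_angstrom` (0.529177210903) and
#'   `gas_constant_R` (1.98720425864e-3 kcal/mol/K).
#' @export
phys_constants <- list(
  hartree_to_kcalmol = 627.5094740631,
  bohr_to_angstrom   = 0.529177210903,
  gas_constant_R     = 1.98720425864e-3
)

#' Convert forces between atomic units and kcal/mol/A
#'
#' Geometry optimization runs in kcal/mol and Angstrom, while the
#' convergence thresholds are quoted in atomic units (Hartree/Bohr for
#' forces, Bohr for displacements). These helpers convert between the two;
#' they are exact inverses of one another.
#'
#' @param f numeric force value(s) in Hartree/Bohr
#'   (for `force_au_to_kcalmol_per_A`) or kcal/mol/A
#'   (for `force_kcalmol_per_A_to_au`).
#' @return numeric force value(s) in the other unit system.
#' @examples
#' force_au_to_kcalmol_per_A(0.00045)  # the max-force threshold, ~0.534
#' @export
force_au_to_kcalmol_per_A <- function(f) {
  stopifnot(all(is.finite(f)))
  f * phys_constants$hartree_to_kcalmol / phys_constants$bohr_to_angstrom
}

#' @rdname force_au_to_kcalmol_per_A
#' @export
force_kcalmol_per_A_to_au <- function(f) {
  stopifnot(all(is.finite(f)))
  f * phys_constants$bohr_to_angstrom / phys_constants$hartree_to_kcalmol
}

angstrom_to_bohr <- function(x) x / phys_constants$bohr_to_angstrom
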