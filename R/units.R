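#' Unit conversion constants
#'
#' All internal computation uses Hartree atomic units (bohr for length,
#' hartree for energy); file I/O and reporting use Angstrom and kJ/mol.
#' These constants define the fixed conversions.
#'
#' @format Named numeric constants:
#' \describe{
#'   \item{ANGSTROM_PER_BOHR}{0.52917721067 Angstrom per bohr}
#'   \item{KJMOL_PER_HARTREE}{2625.4996394798 kJ/mol per hartree}
#' }
#' @name units
NULL

#' @rdname units
#' @export
ANGSTROM_PER_BOHR <- 0.52917721067

#' @rdname units
#' @export
KJMOL_PER_HARTREE <- 2625.4996394798

#' Convert lengths between Angstrom and bohr
#'
#' @param x numeric vector of lengths.
#' @return numeric vector in the target unit.
#' @export
ang_to_bohr <- function(x) x / ANGSTROM_PER_BOHR

#' @rdname ang_to_bohr
#' @export
bohr_to_ang <- function(x) x * ANGSTROM_PER_BOHR

#' Convert energies between hartree and kJ/mol
#'
#' @param x numeric vector of energies.
#' @return numeric vector in the target unit.
#' @export
hartree_to_kjmol <- function(x) x * KJMOL_PER_HARTREE

#' @rdname hartree_to_kjmol
#' @export
kjmol_to_hartree <- function(x) x / KJMOL_PER_HARTREE
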