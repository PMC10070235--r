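# Unit conversions. Internal units are hartree (energy) and bohr (length);
# every file interface speaks eV and Angstrom.

#' Unit conversion constants and helpers
#'
#' `diabex` computes in atomic units (hartree, bohr) and reads/writes files in
#' eV and Angstrom. Conversion factors: 1 hartree = 27.211386 eV,
#' 1 bohr = 0.52917721 Angstrom.
#'
#' @param x numeric vector to convert.
#' @return converted numeric vector.
#' @examples
#' hartree_to_ev(1)        # 27.211386
#' angstrom_to_bohr(0.52917721)  # 1
#' @name units
NULL

HARTREE_EV <- 27.211386
BOHR_ANGSTROM <- 0.52917721

#' @rdname units
#' @export
hartree_to_ev <- function(x) x * HARTREE_EV

#' @rdname units
#' @export
ev_to_hartree <- function(x) x / HARTREE_EV

#' @rdname units
#' @export
bohr_to_angstrom <- function(x) x * BOHR_ANGSTROM

#' @rdname units
#' @export
angstrom_to_bohr <- function(x) x / BOHR_ANGSTROM

# classed error helper so callers can distinguish failure modes
diabex_error <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(paste0("diabex_", class), "diabex_error")))
}

as_unit <- function(x_hartree, unit) {
  unit <- match.arg(unit, c("hartree", "eV"))
  if (unit == "eV") hartree_to_ev(x_hartree) else x_hartree
}
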