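# Element symbol <-> atomic number lookup (periods 1-7).

.element_symbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr", "Y", "Zr",
  "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd",
  "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb",
  "Lu", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg",
  "Tl", "Pb", "Bi", "Po", "At", "Rn", "Fr", "Ra", "Ac", "Th",
  "Pa", "U"
)

#' Convert element symbols to atomic numbers
#'
#' @param symbols character vector of element symbols (case normalised, e.g.
#'   `"C"`, `"Cl"`; `"CL"` as found in some PDB files is accepted).
#' @return integer vector of atomic numbers.
#' @keywords internal
symbol_to_z <- function(symbols) {
  s <- paste0(
    toupper(substr(symbols, 1L, 1L)),
    tolower(substr(symbols, 2L, nchar(symbols)))
  )
  z <- match(s, .element_symbols)
  if (anyNA(z)) {
    abort_input(sprintf(
      "unknown element symbol(s): %s",
      paste(unique(symbols[is.na(z)]), collapse = ", ")
    ))
  }
  as.integer(z)
}

#' Convert atomic numbers to element symbols
#'
#' @param z integer vector of atomic numbers (1-based, <= 92).
#' @return character vector of element symbols.
#' @keywords internal
z_to_symbol <- function(z) {
  if (any(z < 1L | z > length(.element_symbols))) {
    abort_contract("atomic numbers must be between 1 and 92")
  }
  .element_symbols[z]
}
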