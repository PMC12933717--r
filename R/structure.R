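# Core geometry record: element symbols + N x 3 Cartesian coordinates (Angstrom).

# IUPAC element symbols, used to validate structures on construction.
.ELEMENT_SYMBOLS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn",
  "Fr", "Ra", "Ac", "Th", "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf",
  "Es", "Fm", "Md", "No", "Lr", "Rf", "Db", "Sg", "Bh", "Hs", "Mt", "Ds",
  "Rg", "Cn", "Nh", "Fl", "Mc", "Lv", "Ts", "Og"
)

.aefm_error <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "aefm_error")))
}

#' Create a molecular structure
#'
#' The universal geometry record used throughout the package: a vector of
#' element symbols and an N x 3 matrix of Cartesian coordinates in Angstrom.
#'
#' @param elements character vector of element symbols (length N).
#' @param coords numeric N x 3 matrix of coordinates in Angstrom.
#' @param id optional text label (e.g. a reaction id or an XYZ comment line).
#' @return An object of class \code{aefm_structure}: a list with fields
#'   \code{elements}, \code{coords} and \code{id}.
#' @examples
#' h2 <- aefm_structure(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0.74)))
#' n_atoms(h2)
#' @export
aefm_structure <- function(elements, coords, id = NULL) {
  elements <- as.character(elements)
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 3, byrow = TRUE)
  coords <- unname(as.matrix(coords))
  storage.mode(coords) <- "double"
  if (length(elements) < 1L)
    .aefm_error("a structure needs at least one atom", "aefm_invalid_structure")
  if (ncol(coords) != 3L || nrow(coords) != length(elements))
    .aefm_error(sprintf(
      "coords must be %d x 3 (got %d x %d)",
      length(elements), nrow(coords), ncol(coords)), "aefm_invalid_structure")
  bad <- setdiff(unique(elements), .ELEMENT_SYMBOLS)
  if (length(bad))
    .aefm_error(paste0("unrecognized element symbol(s): ",
                       paste(bad, collapse = ", ")), "aefm_invalid_structure")
  if (!all(is.finite(coords)))
    .aefm_error("coordinates must be finite", "aefm_invalid_structure")
  structure(list(elements = elements, coords = coords, id = id),
            class = "aefm_structure")
}

#' @export
print.aefm_structure <- function(x, ...) {
  cat(sprintf("<aefm_structure%s: %d atoms [%s]>\n",
              if (is.null(x$id)) "" else paste0(" ", x$id),
              n_atoms(x), paste(unique(x$elements), collapse = ",")))
  invisible(x)
}

#' Number of atoms in a structure
#' @param x an \code{aefm_structure}.
#' @return integer atom count.
#' @export
n_atoms <- function(x) {
  stopifnot(inherits(x, "aefm_structure"))
  length(x$elements)
}

#' Test for the structure class
#' @param x object to test.
#' @return logical.
#' @export
is_aefm_structure <- function(x) inherits(x, "aefm_structure")

#' Replace the coordinates of a structure
#' @param x an \code{aefm_structure}.
#' @param coords new N x 3 coordinate matrix.
#' @return a structure with identical elements/id and new coordinates.
#' @export
set_coords <- function(x, coords) {
  aefm_structure(x$elements, coords, id = x$id)
}

# Error unless a and b have identical atom counts and element sequences.
.check_same_layout <- function(a, b, what = "structures") {
  stopifnot(is_aefm_structure(a), is_aefm_structure(b))
  if (n_atoms(a) != n_atoms(b) || !identical(a$elements, b$elements))
    .aefm_error(sprintf(
      "%s have mismatched atom counts or element sequences", what),
      "aefm_structure_mismatch")
  invisible(TRUE)
}

# Coordinate accessors that also accept bare matrices (2D toy pathway and
# test doubles run the solver on plain coordinate matrices).
.get_coords <- function(x) if (is_aefm_structure(x)) x$coords else x

.with_coords <- function(x, coords) {
  if (is_aefm_structure(x)) set_coords(x, coords) else coords
}

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
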