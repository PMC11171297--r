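## Molecular geometry container.  Internal coordinates are bohr; constructors
## accept Angstrom because that is what the field's geometry files use.

ELEMENTS <- c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
              "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar",
              "K", "Ca")

element_number <- function(sym) {
  z <- match(sym, ELEMENTS)
  if (any(is.na(z))) {
    stop("unknown element symbol(s): ", paste(sym[is.na(z)], collapse = ", "))
  }
  z
}

#' Build a molecule
#'
#' Creates the geometry container used by the integral and SCF layers.  Only
#' closed-shell singlets are supported: the pair-coupled-cluster framework is
#' restricted to molecules with singlet ground states.
#'
#' @param elements character vector of element symbols.
#' @param coords numeric matrix (n_atom x 3) of Cartesian coordinates.
#' @param unit `"angstrom"` (default) or `"bohr"`.
#' @param charge total molecular charge in units of e.
#' @return an object of class `molecule` with coordinates stored in bohr.
#' @examples
#' h2 <- molecule(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0.74)))
#' @export
molecule <- function(elements, coords, unit = c("angstrom", "bohr"), charge = 0) {
  unit <- match.arg(unit)
  coords <- matrix(as.numeric(coords), ncol = 3)
  if (nrow(coords) != length(elements)) {
    stop("coords must have one row per element")
  }
  if (unit == "angstrom") coords <- coords * BOHR_PER_ANGSTROM
  z <- element_number(elements)
  nelec <- sum(z) - charge
  if (nelec %% 2 != 0) {
    stop("odd electron count: only closed-shell singlets are supported")
  }
  structure(
    list(elements = elements, nuclear_charges = as.numeric(z),
         coords = coords, charge = charge, multiplicity = 1L,
         n_electrons = as.integer(nelec)),
    class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat("Molecule:", paste(x$elements, collapse = " "),
      sprintf(" (charge %+d, %d electrons)\n", x$charge, x$n_electrons))
  ang <- x$coords * ANGSTROM_PER_BOHR
  for (i in seq_along(x$elements)) {
    cat(sprintf("  %-2s %12.6f %12.6f %12.6f\n", x$elements[i],
                ang[i, 1], ang[i, 2], ang[i, 3]))
  }
  invisible(x)
}

#' Build a diatomic along the positive z axis
#'
#' Places atom A at the origin and atom B on the positive z axis, the
#' convention under which a positive mu_z indicates A(-)B(+) polarity.  For
#' heteronuclear dipole-surface work A should be the less electronegative
#' atom.
#'
#' @param a,b element symbols for the atom at the origin and on +z.
#' @param r internuclear distance.
#' @param unit `"angstrom"` (default) or `"bohr"`.
#' @param charge total charge.
#' @return a `molecule`.
#' @export
diatomic <- function(a, b, r, unit = c("angstrom", "bohr"), charge = 0) {
  unit <- match.arg(unit)
  molecule(c(a, b), rbind(c(0, 0, 0), c(0, 0, r)), unit = unit, charge = charge)
}

#' Read an XYZ geometry file
#'
#' Standard XYZ format: atom count, comment line, then `symbol x y z` rows in
#' Angstrom.
#'
#' @param path file path.
#' @param charge total charge (XYZ carries no charge field).
#' @return a `molecule`.
#' @export
read_xyz <- function(path, charge = 0) {
  lines <- readLines(path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("malformed XYZ: first line must be the atom count")
  rows <- lines[3:(2 + n)]
  parts <- strsplit(trimws(rows), "\\s+")
  elements <- vapply(parts, `[[`, "", 1)
  coords <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  molecule(elements, coords, unit = "angstrom", charge = charge)
}

#' Nuclear repulsion energy
#' @param mol a `molecule`.
#' @return energy in hartree.
#' @export
nuclear_repulsion <- function(mol) {
  n <- nrow(mol$coords)
  e <- 0
  if (n < 2) return(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- sqrt(sum((mol$coords[i, ] - mol$coords[j, ])^2))
      e <- e + mol$nuclear_charges[i] * mol$nuclear_charges[j] / r
    }
  }
  e
}

#' Nuclear dipole moment about an origin
#' @param mol a `molecule`.
#' @param origin 3-vector in bohr.
#' @return 3-vector in atomic units (e * bohr).
#' @export
nuclear_dipole <- function(mol, origin = c(0, 0, 0)) {
  drop(crossprod(mol$coords - matrix(origin, nrow(mol$coords), 3, byrow = TRUE),
                 mol$nuclear_charges))
}
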