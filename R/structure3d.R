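#' Molecular structure container
#'
#' A `structure3d` holds an ordered set of atoms with Cartesian coordinates
#' in Angstrom, residue/chain identity and a per-atom restraint weight in
#' kcal/mol/A^2. The weight channel drives the frozen/active protocol used
#' throughout the package: `-1` marks a frozen atom, `0` a free atom and a
#' positive value the force constant of a harmonic positional restraint.
#'
#' @param element character vector of chemical symbols (e.g. "C", "Cl").
#' @param coords numeric N x 3 matrix of coordinates in Angstrom.
#' @param residue_name character vector (recycled) of residue names.
#' @param residue_id integer vector (recycled) of residue numbers.
#' @param chain_id character vector (recycled) of chain identifiers.
#' @param atom_name character vector (recycled) of atom names; defaults to
#'   the element symbol.
#' @param restraint_weight numeric vector (recycled), kcal/mol/A^2; must be
#'   >= -1 where -1 is the frozen sentinel.
#' @param label short free-text label for the structure.
#' @return An object of class `structure3d`.
#' @examples
#' s <- structure3d(c("O", "H", "H"),
#'                  rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)))
#' n_atoms(s)
#' @export
structure3d <- function(element, coords, residue_name = "LIG",
                        residue_id = 1L, chain_id = "A",
                        atom_name = element, restraint_weight = 0,
                        label = "") {
  coords <- as_coords_matrix(coords)
  n <- nrow(coords)
  element <- toupper(as.character(element))
  if (length(element) != n)
    stop("'element' must have one entry per atom")
  bad <- !(element %in% names(.element_masses))
  if (any(bad))
    stop("unrecognized element symbol(s): ",
         paste(unique(element[bad]), collapse = ", "))
  if (any(!is.finite(coords)))
    stop("coordinates must be finite")
  restraint_weight <- rep_len(as.numeric(restraint_weight), n)
  if (any(restraint_weight < -1))
    stop("restraint_weight must be >= -1 (-1 is the frozen sentinel)")
  atoms <- data.frame(
    element = element,
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    residue_name = rep_len(as.character(residue_name), n),
    residue_id = rep_len(as.integer(residue_id), n),
    chain_id = rep_len(as.character(chain_id), n),
    atom_name = rep_len(as.character(atom_name), n),
    restraint_weight = restraint_weight,
    stringsAsFactors = FALSE
  )
  new_structure3d(atoms, label)
}

new_structure3d <- function(atoms, label = "") {
  stopifnot(is.data.frame(atoms))
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, label = as.character(label)),
            class = "structure3d")
}

as_coords_matrix <- function(coords) {
  coords <- as.matrix(coords)
  if (is.vector(coords)) coords <- matrix(coords, ncol = 3, byrow = TRUE)
  if (ncol(coords) != 3)
    stop("coordinates must be an N x 3 matrix")
  storage.mode(coords) <- "double"
  unname(coords)
}

# Monoisotopic-ish masses; used only for symbol validation and H detection.
.element_masses <- c(
  H = 1.008, D = 2.014, HE = 4.003, LI = 6.94, BE = 9.012, B = 10.81,
  C = 12.011, N = 14.007, O = 15.999, F = 18.998, NE = 20.18, "NA" = 22.99,
  MG = 24.305, AL = 26.982, SI = 28.085, P = 30.974, S = 32.06,
  CL = 35.45, AR = 39.95, K = 39.098, CA = 40.078, MN = 54.938,
  FE = 55.845, CO = 58.933, NI = 58.693, CU = 63.546, ZN = 65.38,
  SE = 78.971, BR = 79.904, I = 126.904
)

#' @export
print.structure3d <- function(x, ...) {
  a <- x$atoms
  nfro <- sum(a$restraint_weight == -1)
  nact <- sum(a$restraint_weight > 0)
  cat(sprintf("structure3d%s: %d atoms, %d residues, %d chain(s)\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              nrow(a), length(unique(paste(a$chain_id, a$residue_id))),
              length(unique(a$chain_id))))
  cat(sprintf("  elements: %s\n",
              paste(names(sort(table(a$element), decreasing = TRUE)),
                    collapse = " ")))
  if (nfro + nact > 0)
    cat(sprintf("  restraints: %d frozen, %d harmonically restrained, %d free\n",
                nfro, nact, nrow(a) - nfro - nact))
  invisible(x)
}

#' Number of atoms in a structure
#' @param s a `structure3d`.
#' @return integer atom count.
#' @export
n_atoms <- function(s) nrow(s$atoms)

#' Extract or replace coordinates
#'
#' @param s a `structure3d`.
#' @return `get_coords` returns the N x 3 coordinate matrix (Angstrom).
#' @export
get_coords <- function(s) {
  m <- as.matrix(s$atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

#' @rdname get_coords
#' @param coords replacement N x 3 matrix.
#' @return `set_coords` returns the modified structure.
#' @export
set_coords <- function(s, coords) {
  coords <- as_coords_matrix(coords)
  if (nrow(coords) != n_atoms(s))
    stop("replacement coordinates must match the atom count")
  s$atoms$x <- coords[, 1]
  s$atoms$y <- coords[, 2]
  s$atoms$z <- coords[, 3]
  s
}

#' Concatenate structures
#'
#' Atom order is receptor-style: atoms of `...` are appended in the order
#' given, preserving each block's internal order.
#' @param ... `structure3d` objects.
#' @param label label for the combined structure.
#' @return a `structure3d` containing all atoms.
#' @export
combine_structures <- function(..., label = "complex") {
  parts <- list(...)
  stopifnot(length(parts) >= 1,
            all(vapply(parts, inherits, logical(1), "structure3d")))
  new_structure3d(do.call(rbind, lapply(parts, function(p) p$atoms)), label)
}

#' Subset a structure by atom indices
#' @param s a `structure3d`.
#' @param idx integer or logical index vector over atoms.
#' @param label optional new label.
#' @return a `structure3d` with the selected atoms, order preserved.
#' @export
subset_atoms <- function(s, idx, label = s$label) {
  atoms <- s$atoms[idx, , drop = FALSE]
  if (nrow(atoms) == 0) stop("subset selects no atoms")
  rownames(atoms) <- NULL
  new_structure3d(atoms, label)
}

#' Logical mask of heavy (non-hydrogen) atoms
#' @param s a `structure3d`.
#' @return logical vector, TRUE for non-hydrogen atoms.
#' @export
heavy_atoms <- function(s) !(s$atoms$element %in% c("H", "D"))
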