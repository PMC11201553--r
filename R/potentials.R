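#' Construct an energy model
#'
#' An `energy_model` is the contract consumed by the optimizer: a function
#' mapping an N x 3 coordinate matrix (Angstrom) to a potential energy
#' (kcal/mol) and per-atom forces (kcal/mol/A, the negative energy
#' gradient).
#'
#' @param eval_fn function(coords) returning `list(energy =, forces =)`.
#' @param elements character vector of supported element symbols, or
#'   `"any"`.
#' @param label short backend name.
#' @return an object of class `energy_model`.
#' @export
energy_model <- function(eval_fn, elements = "any", label = "custom") {
  stopifnot(is.function(eval_fn))
  structure(list(eval = eval_fn, elements = toupper(elements),
                 label = label),
            class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat(sprintf("energy_model '%s' (elements: %s)\n", x$label,
              paste(x$elements, collapse = " ")))
  invisible(x)
}

#' Evaluate an energy model
#'
#' @param model an [energy_model()].
#' @param coords N x 3 coordinate matrix in Angstrom, or a `structure3d`.
#' @return `list(energy, forces)`; energy in kcal/mol, forces N x 3 in
#'   kcal/mol/A.
#' @export
evaluate_energy <- function(model, coords) {
  stopifnot(inherits(model, "energy_model"))
  if (inherits(coords, "structure3d")) {
    check_model_elements(model, coords)
    coords <- get_coords(coords)
  }
  coords <- as_coords_matrix(coords)
  out <- model$eval(coords)
  if (!is.finite(out$energy))
    stop("energy model '", model$label, "' returned a non-finite energy")
  out$forces <- as_coords_matrix(out$forces)
  out
}

#' Check that a model supports a structure's elements
#'
#' @param model an [energy_model()].
#' @param s a `structure3d` (or character vector of element symbols).
#' @return invisibly TRUE; errors naming the offending symbol(s) otherwise.
#' @export
check_model_elements <- function(model, s) {
  if (identical(model$elements, "ANY")) return(invisible(TRUE))
  el <- if (inherits(s, "structure3d")) unique(s$atoms$element) else
    unique(toupper(s))
  bad <- setdiff(el, model$elements)
  if (length(bad))
    stop("element(s) not supported by the '", model$label, "' potential: ",
         paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Lennard-Jones pair potential
#'
#' Pairwise-additive 12-6 potential over all atom pairs,
#' \eqn{E = \sum_{i<j} 4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6]}, with
#' analytic forces. Used as the package's transparent test potential: its
#' minimum-energy pair distance \eqn{2^{1/6}\sigma} and well depth
#' \eqn{-\epsilon} are known in closed form.
#'
#' @param epsilon well depth, kcal/mol (> 0).
#' @param sigma zero-crossing distance, Angstrom (> 0).
#' @param cutoff pair cutoff distance in Angstrom; pairs beyond it
#'   contribute nothing (plain truncation). `Inf` (default) disables it.
#' @return an [energy_model()].
#' @export
lj_pair_model <- function(epsilon = 1, sigma = 1, cutoff = Inf) {
  stopifnot(epsilon > 0, sigma > 0, cutoff > 0)
  eval_fn <- function(coords) {
    n <- nrow(coords)
    energy <- 0
    forces <- matrix(0, n, 3)
    if (n >= 2) {
      pr <- utils::combn(n, 2)
      dvec <- coords[pr[1, ], , drop = FALSE] - coords[pr[2, ], , drop = FALSE]
      r2 <- rowSums(dvec^2)
      if (any(r2 == 0)) stop("coincident atoms: LJ energy undefined at r = 0")
      keep <- r2 <= cutoff^2
      if (any(keep)) {
        r2k <- r2[keep]
        sr6 <- (sigma^2 / r2k)^3
        energy <- sum(4 * epsilon * (sr6^2 - sr6))
        # dE/dr * (1/r) pair coefficient; force on i is -coef * (ri - rj)
        coef <- 24 * epsilon * (2 * sr6^2 - sr6) / r2k
        fpair <- dvec[keep, , drop = FALSE] * coef
        ik <- pr[1, keep]; jk <- pr[2, keep]
        for (d in 1:3) {
          forces[, d] <- forces[, d] +
            tabulate_sum(ik, fpair[, d], n) - tabulate_sum(jk, fpair[, d], n)
        }
      }
    }
    list(energy = energy, forces = forces)
  }
  energy_model(eval_fn, "any",
               sprintf("lj(eps=%g, sigma=%g)", epsilon, sigma))
}

tabulate_sum <- function(idx, val, n) {
  out <- numeric(n)
  s <- rowsum(val, idx)
  out[as.integer(rownames(s))] <- s
  out
}

#' Isotropic harmonic well
#'
#' Convex test potential \eqn{E = k \sum_i |r_i - c|^2} with forces
#' \eqn{-2k(r_i - c)}; its unique minimum (all atoms at the center) makes
#' optimizer behaviour fully predictable.
#'
#' @param k force constant, kcal/mol/A^2 (> 0).
#' @param center 3-vector well center, Angstrom.
#' @return an [energy_model()].
#' @export
harmonic_well_model <- function(k = 1, center = c(0, 0, 0)) {
  stopifnot(k > 0, length(center) == 3)
  center <- as.numeric(center)
  eval_fn <- function(coords) {
    d <- sweep(coords, 2, center)
    list(energy = k * sum(d^2), forces = -2 * k * d)
  }
  energy_model(eval_fn, "any", sprintf("harmonic(k=%g)", k))
}

#' Harmonic positional restraint
#'
#' Restrains selected atoms to reference positions with
#' \eqn{E = k \sum_i |r_i - r_i^0|^2} (no 1/2 factor; `k` is the
#' "temperature coefficient" written to the B-factor column, 5 kcal/mol/A^2
#' for active pocket atoms by default).
#'
#' @param atom_indices integer indices of restrained atoms.
#' @param reference_coords matrix of reference positions, one row per
#'   restrained atom, Angstrom.
#' @param weight force constant k, kcal/mol/A^2 (> 0).
#' @return an object of class `positional_restraint`.
#' @export
positional_restraint <- function(atom_indices, reference_coords, weight) {
  reference_coords <- as_coords_matrix(reference_coords)
  atom_indices <- as.integer(atom_indices)
  stopifnot(weight > 0, length(atom_indices) == nrow(reference_coords),
            all(atom_indices >= 1), !anyDuplicated(atom_indices))
  structure(list(atom_indices = atom_indices,
                 reference_coords = reference_coords,
                 weight = weight),
            class = c("positional_restraint", "restraint"))
}

#' Evaluate restraint terms
#'
#' @param restraint a [positional_restraint()] or [torsion_restraint()].
#' @param coords full N x 3 coordinate matrix, Angstrom.
#' @return `list(energy, forces)` with forces over all N atoms (nonzero
#'   only on the atoms the restraint touches).
#' @export
restraint_energy_forces <- function(restraint, coords) {
  UseMethod("restraint_energy_forces")
}

#' @export
restraint_energy_forces.positional_restraint <- function(restraint, coords) {
  coords <- as_coords_matrix(coords)
  idx <- restraint$atom_indices
  if (max(idx) > nrow(coords))
    stop("restraint index out of range: ", max(idx))
  d <- coords[idx, , drop = FALSE] - restraint$reference_coords
  forces <- matrix(0, nrow(coords), 3)
  forces[idx, ] <- -2 * restraint$weight * d
  list(energy = restraint$weight * sum(d^2), forces = forces)
}

#' Harmonic torsional restraint
#'
#' Restrains the dihedral angle defined by four atoms to a target value,
#' \eqn{E = k\,\Delta\phi^2} with \eqn{\Delta\phi} the signed angular
#' difference wrapped to (-180, 180] degrees and expressed in radians.
#'
#' @param atom_quadruple four distinct atom indices defining the dihedral.
#' @param target_angle target dihedral in degrees, in (-180, 180].
#' @param weight force constant, kcal/mol/rad^2 (> 0).
#' @return an object of class `torsion_restraint`.
#' @export
torsion_restraint <- function(atom_quadruple, target_angle, weight) {
  atom_quadruple <- as.integer(atom_quadruple)
  stopifnot(length(atom_quadruple) == 4,
            !anyDuplicated(atom_quadruple),
            weight > 0, target_angle > -180, target_angle <= 180)
  structure(list(atom_quadruple = atom_quadruple,
                 target_angle = target_angle, weight = weight),
            class = c("torsion_restraint", "restraint"))
}

#' Dihedral angle of four points
#'
#' @param p 4 x 3 matrix of coordinates.
#' @return signed dihedral angle in radians, in (-pi, pi] (IUPAC sign
#'   convention).
#' @export
dihedral_angle <- function(p) {
  b1 <- p[2, ] - p[1, ]
  b2 <- p[3, ] - p[2, ]
  b3 <- p[4, ] - p[3, ]
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20)
    stop("dihedral undefined: collinear atom triple")
  atan2(sum(cross3(n1, n2) * b2) / sqrt(sum(b2^2)), sum(n1 * n2))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Analytic gradient of the dihedral angle w.r.t. the four atom positions
# (van Schaik et al. formulation); rows sum to zero (translation invariance).
dihedral_gradient <- function(p) {
  b1 <- p[2, ] - p[1, ]
  b2 <- p[3, ] - p[2, ]
  b3 <- p[4, ] - p[3, ]
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  n1sq <- sum(n1^2); n2sq <- sum(n2^2); bnorm <- sqrt(sum(b2^2))
  if (n1sq < 1e-20 || n2sq < 1e-20)
    stop("dihedral undefined: collinear atom triple")
  g1 <- -(bnorm / n1sq) * n1
  g4 <- (bnorm / n2sq) * n2
  c12 <- sum(b1 * b2) / sum(b2^2)
  c32 <- sum(b3 * b2) / sum(b2^2)
  g2 <- -(1 + c12) * g1 + c32 * g4
  g3 <- c12 * g1 - (1 + c32) * g4
  rbind(g1, g2, g3, g4, deparse.level = 0)
}

#' @export
restraint_energy_forces.torsion_restraint <- function(restraint, coords) {
  coords <- as_coords_matrix(coords)
  idx <- restraint$atom_quadruple
  if (max(idx) > nrow(coords))
    stop("restraint index out of range: ", max(idx))
  p <- coords[idx, , drop = FALSE]
  phi <- dihedral_angle(p)
  dphi <- wrap_angle(phi - restraint$target_angle * pi / 180)
  grad <- dihedral_gradient(p)
  forces <- matrix(0, nrow(coords), 3)
  forces[idx, ] <- -2 * restraint$weight * dphi * grad
  list(energy = restraint$weight * dphi^2, forces = forces)
}

# wrap a radian angle difference to (-pi, pi]
wrap_angle <- function(x) {
  w <- x - 2 * pi * round(x / (2 * pi))
  if (w <= -pi) w <- w + 2 * pi
  w
}

#' Compose a base potential with restraints and a frozen mask
#'
#' Energy and forces are the sums over the base model and all restraint
#' terms; forces on frozen atoms are zeroed after summation. Frozen atoms
#' still contribute to the base potential energy (they are a static
#' environment) -- the frozen flag suppresses their motion, it is not an
#' energy term.
#'
#' @param base an [energy_model()].
#' @param restraints list of [positional_restraint()] /
#'   [torsion_restraint()] objects.
#' @param frozen_mask logical vector, one entry per atom (TRUE = frozen),
#'   or NULL for none.
#' @return an [energy_model()] evaluating the composite.
#' @export
compose_potential <- function(base, restraints = list(), frozen_mask = NULL) {
  stopifnot(inherits(base, "energy_model"))
  if (inherits(restraints, "restraint")) restraints <- list(restraints)
  stopifnot(all(vapply(restraints, inherits, logical(1), "restraint")))
  eval_fn <- function(coords) {
    if (!is.null(frozen_mask) && length(frozen_mask) != nrow(coords))
      stop("frozen mask length (", length(frozen_mask),
           ") does not match atom count (", nrow(coords), ")")
    out <- base$eval(coords)
    energy <- out$energy
    forces <- out$forces
    for (r in restraints) {
      term <- restraint_energy_forces(r, coords)
      energy <- energy + term$energy
      forces <- forces + term$forces
    }
    if (!is.null(frozen_mask)) forces[frozen_mask, ] <- 0
    list(energy = energy, forces = forces)
  }
  energy_model(eval_fn, base$elements,
               sprintf("%s + %d restraint(s)%s", base$label,
                       length(restraints),
                       if (is.null(frozen_mask) || !any(frozen_mask)) ""
                       else sprintf(" + %d frozen", sum(frozen_mask))))
}

#' Central finite-difference forces
#'
#' Numerical forces \eqn{-\partial E/\partial r} by central differences;
#' intended for validating analytic gradients of an energy backend.
#'
#' @param model an [energy_model()].
#' @param coords N x 3 coordinate matrix, Angstrom.
#' @param h displacement step in Angstrom (1e-5 suits analytic
#'   potentials; use ~1e-4 for ML potentials with less smooth surfaces).
#' @return N x 3 matrix of numerical forces, kcal/mol/A.
#' @export
numerical_forces <- function(model, coords, h = 1e-5) {
  coords <- as_coords_matrix(coords)
  f <- matrix(0, nrow(coords), 3)
  for (i in seq_len(nrow(coords))) {
    for (d in 1:3) {
      cp <- coords; cp[i, d] <- cp[i, d] + h
      cm <- coords; cm[i, d] <- cm[i, d] - h
      f[i, d] <- -(model$eval(cp)$energy - model$eval(cm)$energy) / (2 * h)
    }
  }
  f
}
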