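#' Truncate a receptor around its bound ligand
#'
#' Keeps every residue that has at least one atom within `radius` of the
#' geometric center of the ligand, and keeps kept residues whole. The
#' protocol range is 8-15 Angstrom; values outside it are allowed with a
#' warning. Where truncation severs a peptide backbone bond (a kept
#' residue whose sequence neighbour is discarded), the dangling C or N
#' atom is capped with a hydrogen placed along the former bond vector at
#' 1.09 Angstrom; residues lacking named C/N backbone atoms (e.g.
#' nucleotides or toy systems) are left uncapped.
#'
#' @param receptor full receptor `structure3d`.
#' @param ligand ligand `structure3d` (defines the pocket center).
#' @param radius truncation radius from the ligand center, Angstrom.
#' @return the truncated pocket as a `structure3d`.
#' @export
truncate_receptor <- function(receptor, ligand, radius = 12) {
  stopifnot(inherits(receptor, "structure3d"), n_atoms(receptor) > 0,
            inherits(ligand, "structure3d"), n_atoms(ligand) > 0)
  if (radius < 8 || radius > 15)
    warning("truncation radius ", radius,
            " A is outside the usual 8-15 A protocol range")
  center <- colMeans(get_coords(ligand))
  rc <- get_coords(receptor)
  dist2 <- rowSums(sweep(rc, 2, center)^2)
  a <- receptor$atoms
  reskey <- paste(a$chain_id, a$residue_id)
  hit <- tapply(dist2 <= radius^2, reskey, any)
  keep_res <- names(hit)[hit]
  if (length(keep_res) == 0)
    stop("no residue within ", radius, " A of the ligand center")
  keep <- reskey %in% keep_res
  pocket <- subset_atoms(receptor, keep, label = "pocket")
  caps <- backbone_caps(receptor, keep)
  if (!is.null(caps)) pocket <- combine_structures(pocket, caps,
                                                   label = "pocket")
  pocket
}

# hydrogen caps for peptide C-N bonds severed by residue truncation
backbone_caps <- function(receptor, keep) {
  a <- receptor$atoms
  rc <- get_coords(receptor)
  cap <- list()
  add_cap <- function(from_i, to_i, res_row) {
    v <- rc[to_i, ] - rc[from_i, ]
    nv <- sqrt(sum(v^2))
    if (nv < 1e-8) return()
    pos <- rc[from_i, ] + 1.09 * v / nv
    cap[[length(cap) + 1L]] <<- data.frame(
      element = "H", x = pos[1], y = pos[2], z = pos[3],
      residue_name = res_row$residue_name, residue_id = res_row$residue_id,
      chain_id = res_row$chain_id, atom_name = "H",
      restraint_weight = 0, stringsAsFactors = FALSE)
  }
  for (i in which(keep)) {
    nm <- trimws(a$atom_name[i])
    if (nm == "C") {
      j <- which(a$chain_id == a$chain_id[i] &
                   a$residue_id == a$residue_id[i] + 1L &
                   trimws(a$atom_name) == "N")
      if (length(j) == 1 && !keep[j]) add_cap(i, j, a[i, ])
    } else if (nm == "N") {
      j <- which(a$chain_id == a$chain_id[i] &
                   a$residue_id == a$residue_id[i] - 1L &
                   trimws(a$atom_name) == "C")
      if (length(j) == 1 && !keep[j]) add_cap(i, j, a[i, ])
    }
  }
  if (length(cap) == 0) return(NULL)
  new_structure3d(do.call(rbind, cap), "caps")
}

#' Assign frozen and active regions of a binding pocket
#'
#' Splits the pocket atoms at a boundary distance from the ligand: a
#' receptor atom whose minimum distance to any ligand atom is `<=
#' boundary` (inclusive; atom centers, hydrogens included) belongs to the
#' active part and receives a harmonic positional restraint of weight
#' `active_weight` to its input position; all other receptor atoms are
#' frozen and flagged with the `-1` sentinel weight. Ligand atoms belong
#' to neither set and move freely.
#'
#' @param pocket truncated receptor `structure3d`.
#' @param ligand ligand `structure3d`.
#' @param boundary region boundary distance, Angstrom (default 2.5).
#' @param active_weight restraint force constant for active atoms,
#'   kcal/mol/A^2 (default 5).
#' @param frozen_flag sentinel weight written for frozen atoms
#'   (default -1).
#' @return an object of class `region_assignment` with `frozen_indices`,
#'   `active_indices`, per-atom `weights`, and `reference_coords`.
#' @export
assign_regions <- function(pocket, ligand, boundary = 2.5,
                           active_weight = 5, frozen_flag = -1) {
  stopifnot(inherits(pocket, "structure3d"), n_atoms(pocket) > 0,
            inherits(ligand, "structure3d"), n_atoms(ligand) > 0,
            boundary > 0, active_weight > 0)
  pc <- get_coords(pocket)
  lc <- get_coords(ligand)
  # min distance from each pocket atom to any ligand atom
  mind2 <- apply(pc, 1, function(p) min(colSums((t(lc) - p)^2)))
  active <- mind2 <= boundary^2
  weights <- ifelse(active, active_weight, frozen_flag)
  structure(list(frozen_indices = which(!active),
                 active_indices = which(active),
                 weights = weights,
                 reference_coords = pc,
                 boundary = boundary,
                 active_weight = active_weight,
                 frozen_flag = frozen_flag),
            class = "region_assignment")
}

#' @export
print.region_assignment <- function(x, ...) {
  cat(sprintf(paste0("region_assignment: %d active (restrained at %g",
                     " kcal/mol/A^2), %d frozen (boundary %g A)\n"),
              length(x$active_indices), x$active_weight,
              length(x$frozen_indices), x$boundary))
  invisible(x)
}

#' Stamp region weights into a pocket structure
#'
#' Writes the per-atom weights of a [assign_regions()] result into the
#' structure's restraint-weight channel so that [write_pdb()] encodes the
#' protocol in the B-factor column (-1.00 frozen, 5.00 active).
#'
#' @param pocket the pocket `structure3d` the assignment was made for.
#' @param assignment a `region_assignment`.
#' @return the pocket with updated restraint weights.
#' @export
apply_region_weights <- function(pocket, assignment) {
  stopifnot(inherits(assignment, "region_assignment"),
            n_atoms(pocket) == length(assignment$weights))
  pocket$atoms$restraint_weight <- assignment$weights
  pocket
}

#' Binding energy from complex and component energies
#'
#' \deqn{\Delta E_{bind} = E_{com} - E_{rec} - E_{lig}}
#'
#' @param E_com,E_rec,E_lig energies of the optimized complex, the
#'   receptor and the ligand, kcal/mol.
#' @return the binding energy, kcal/mol.
#' @export
binding_energy <- function(E_com, E_rec, E_lig) {
  if (!all(is.finite(c(E_com, E_rec, E_lig))))
    stop("binding energy requires finite component energies")
  E_com - E_rec - E_lig
}

#' Refine one docked pose and score its binding energy
#'
#' Builds the complex (pocket atoms first, then pose atoms), composes the
#' potential with the harmonic restraints of the active region and the
#' frozen mask, minimizes with [cgbs_minimize()], and evaluates the
#' rescoring energies on the bare (unrestrained) potential:
#' `E_com` is the single-point energy of the optimized complex, and by
#' default `E_rec`/`E_lig` are single-point energies of the receptor and
#' ligand at their in-complex optimized coordinates (rigid
#' decomposition). With `relax_parts = TRUE` the two components are
#' instead re-minimized separately (the receptor under its own
#' restraints/frozen mask) before the single points.
#'
#' @param pocket truncated receptor `structure3d`.
#' @param pose ligand pose `structure3d` (never positionally restrained).
#' @param assignment a [assign_regions()] result for `pocket`.
#' @param model base [energy_model()] (no restraints).
#' @param criteria a [convergence_criteria()].
#' @param control a [cgbs_control()].
#' @param pose_id identifier stored in the score row.
#' @param relax_parts logical; relax receptor and ligand separately
#'   before their single-point energies.
#' @return `list(structure = optimized complex, score = one-row
#'   data.frame)` with columns `pose_id, E_com, E_rec, E_lig,
#'   delta_E_bind, converged`.
#' @export
refine_pose <- function(pocket, pose, assignment, model,
                        criteria = convergence_criteria(),
                        control = cgbs_control(),
                        pose_id = "pose", relax_parts = FALSE) {
  stopifnot(inherits(assignment, "region_assignment"),
            n_atoms(pocket) == length(assignment$weights))
  check_model_elements(model, pocket)
  check_model_elements(model, pose)
  np <- n_atoms(pocket)
  complex <- combine_structures(pocket, pose, label = "complex")
  frozen <- rep(FALSE, n_atoms(complex))
  frozen[assignment$frozen_indices] <- TRUE
  restraints <- region_restraints(assignment)
  composite <- compose_potential(model, restraints, frozen)
  fit <- cgbs_minimize(composite, get_coords(complex), frozen,
                       criteria, control)
  xc <- fit$final_coords
  rec_idx <- seq_len(np)
  lig_idx <- seq.int(np + 1L, n_atoms(complex))
  E_com <- model$eval(xc)$energy
  if (relax_parts) {
    rec_fit <- cgbs_minimize(compose_potential(model, restraints,
                                               frozen[rec_idx]),
                             xc[rec_idx, , drop = FALSE],
                             frozen[rec_idx], criteria, control)
    lig_fit <- cgbs_minimize(model, xc[lig_idx, , drop = FALSE],
                             NULL, criteria, control)
    E_rec <- model$eval(rec_fit$final_coords)$energy
    E_lig <- model$eval(lig_fit$final_coords)$energy
  } else {
    E_rec <- model$eval(xc[rec_idx, , drop = FALSE])$energy
    E_lig <- model$eval(xc[lig_idx, , drop = FALSE])$energy
  }
  score <- data.frame(pose_id = pose_id, E_com = E_com, E_rec = E_rec,
                      E_lig = E_lig,
                      delta_E_bind = binding_energy(E_com, E_rec, E_lig),
                      converged = fit$converged,
                      stringsAsFactors = FALSE)
  list(structure = set_coords(complex, xc), score = score, fit = fit)
}

# one positional restraint per distinct active weight
region_restraints <- function(assignment) {
  act <- assignment$active_indices
  if (length(act) == 0) return(list())
  w <- assignment$weights[act]
  lapply(unique(w), function(wi) {
    idx <- act[w == wi]
    positional_restraint(idx,
                         assignment$reference_coords[idx, , drop = FALSE],
                         wi)
  })
}

#' Refine and rank a set of docked poses
#'
#' Applies [refine_pose()] to every pose and ranks the resulting binding
#' energies with [rank_poses()].
#'
#' @param pocket,assignment,model,criteria,control as in [refine_pose()].
#' @param poses list of ligand pose `structure3d` objects (e.g. models of
#'   a multi-model PDB, in docking-rank order).
#' @param ... passed on to [refine_pose()].
#' @return `list(scores = pose_scores data.frame, structures = list of
#'   optimized complexes)`.
#' @export
refine_pose_set <- function(pocket, poses, assignment, model,
                            criteria = convergence_criteria(),
                            control = cgbs_control(), ...) {
  stopifnot(is.list(poses), length(poses) >= 1)
  ids <- sprintf("pose_%02d", seq_along(poses))
  res <- lapply(seq_along(poses), function(i)
    refine_pose(pocket, poses[[i]], assignment, model, criteria, control,
                pose_id = ids[i], ...))
  scores <- rank_poses(do.call(rbind, lapply(res, `[[`, "score")))
  list(scores = scores, structures = lapply(res, `[[`, "structure"))
}

#' Rank poses by binding energy
#'
#' Ascending \eqn{\Delta E_{bind}}: the most negative binding energy gets
#' rank 1. Ties are broken by input order (stable ranking), so the input
#' docking order is preserved among equal scores.
#'
#' @param scores data.frame with a `delta_E_bind` column (e.g. rbind-ed
#'   [refine_pose()] scores).
#' @return the same data.frame with a `rank` column, input order
#'   preserved, classed `pose_scores`.
#' @export
rank_poses <- function(scores) {
  stopifnot(is.data.frame(scores), nrow(scores) >= 1,
            "delta_E_bind" %in% names(scores))
  if (any(!is.finite(scores$delta_E_bind)))
    stop("non-finite binding energy in scores")
  scores$rank <- rank(scores$delta_E_bind, ties.method = "first")
  class(scores) <- c("pose_scores", "data.frame")
  scores
}

#' @export
print.pose_scores <- function(x, ...) {
  cat(sprintf("pose_scores: %d pose(s); best dEbind %.4f kcal/mol (%s)\n",
              nrow(x), min(x$delta_E_bind), x$pose_id[which.min(x$rank)]))
  print.data.frame(x, digits = 6)
  invisible(x)
}
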