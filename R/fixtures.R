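#' Deterministic Lennard-Jones toy complex
#'
#' Builds a toy receptor/ligand pair for end-to-end pipeline tests
#' without any docking engine. Receptor atoms sit on a jittered cubic
#' lattice; the native ligand is placed at the global minimum of the
#' frozen-receptor landscape, located by a dense grid scan of the
#' probe-atom interaction energy followed by local relaxation of the
#' best candidate basins, so the native site is the deepest adsorption
#' site of the actual jittered cluster. A 1-atom receptor plus 1-atom
#' ligand is an LJ dimer at its analytic minimum \eqn{2^{1/6}\sigma}.
#' All randomness (lattice jitter) comes from `seed`; identical seeds
#' give identical coordinates.
#'
#' @param n_receptor_atoms,n_ligand_atoms atom counts (>= 1).
#' @param epsilon,sigma LJ parameters of the intended test potential.
#' @param seed integer seed controlling the lattice jitter.
#' @param jitter uniform lattice jitter amplitude, units of sigma.
#' @return `list(receptor, ligand)` of `structure3d` objects; each
#'   receptor atom is its own single-atom residue (chain R), the ligand
#'   is one residue on chain L.
#' @export
make_toy_complex <- function(n_receptor_atoms, n_ligand_atoms = 1,
                             epsilon = 1, sigma = 1, seed = 1L,
                             jitter = 0.05) {
  stopifnot(n_receptor_atoms >= 1, n_ligand_atoms >= 1,
            epsilon > 0, sigma > 0)
  r_min <- 2^(1 / 6) * sigma
  spacing <- 1.5 * sigma
  side <- ceiling(n_receptor_atoms^(1 / 3))
  grid <- as.matrix(expand.grid(x = seq_len(side), y = seq_len(side),
                                z = seq_len(side)))
  grid <- grid[order(grid[, 3], grid[, 2], grid[, 1]), , drop = FALSE]
  grid <- grid[seq_len(n_receptor_atoms), , drop = FALSE] * spacing
  rec_xyz <- withr::with_seed(seed, {
    grid + matrix(stats::runif(3 * n_receptor_atoms, -jitter * sigma,
                               jitter * sigma),
                  ncol = 3)
  })
  site <- best_adsorption_site(grid, rec_xyz, spacing, r_min,
                               epsilon, sigma)
  lig_xyz <- cbind(site[1] + (seq_len(n_ligand_atoms) - 1) * r_min,
                   site[2], site[3])
  receptor <- structure3d(rep("C", n_receptor_atoms), rec_xyz,
                          residue_name = "REC",
                          residue_id = seq_len(n_receptor_atoms),
                          chain_id = "R", label = "toy receptor")
  ligand <- structure3d(rep("C", n_ligand_atoms), lig_xyz,
                        residue_name = "LIG", residue_id = 1L,
                        chain_id = "L", label = "toy ligand")
  list(receptor = receptor, ligand = ligand)
}

#' Rigid-body decoy poses of a ligand
#'
#' Emulates the ranked pose set a docking engine would emit: each decoy
#' is a rigid perturbation of the native pose, rotated about its centroid
#' by a uniform-axis/uniform-angle rotation of at most `max_rotation`
#' degrees and translated by at most `max_translation` Angstrom
#' (uniform direction, uniform magnitude). With `include_native = TRUE`
#' the first decoy is the native pose itself. Fully deterministic per
#' seed.
#'
#' @param native the native ligand `structure3d`.
#' @param n_decoys number of poses to generate (>= 1).
#' @param max_translation maximum translation, Angstrom.
#' @param max_rotation maximum rotation angle, degrees.
#' @param seed integer seed.
#' @param include_native make decoy 1 the unperturbed native pose.
#' @return list of `structure3d` poses.
#' @export
make_decoys <- function(native, n_decoys = 10, max_translation = 2,
                        max_rotation = 30, seed = 1L,
                        include_native = FALSE) {
  stopifnot(inherits(native, "structure3d"), n_atoms(native) >= 1,
            n_decoys >= 1, max_translation >= 0, max_rotation >= 0)
  xyz <- get_coords(native)
  centroid <- colMeans(xyz)
  withr::with_seed(seed, lapply(seq_len(n_decoys), function(i) {
    if (include_native && i == 1) return(native)
    axis <- random_unit_vector()
    angle <- stats::runif(1, 0, max_rotation) * pi / 180
    shift <- random_unit_vector() * stats::runif(1, 0, max_translation)
    R <- rotation_matrix(axis, angle)
    moved <- sweep(sweep(xyz, 2, centroid) %*% t(R), 2, centroid + shift,
                   FUN = "+")
    set_coords(native, moved)
  }))
}

# Deepest single-atom LJ adsorption site on the jittered lattice: the
# global minimum of the frozen-receptor landscape. A dense grid scan of
# the probe's cross-interaction energy locates candidate basins; the
# best, mutually distinct grid points are then locally relaxed and the
# deepest relaxed position wins. For a single receptor atom this is the
# exact dimer minimum.
best_adsorption_site <- function(grid, rec_xyz, spacing, r_min,
                                 epsilon, sigma) {
  n <- nrow(rec_xyz)
  if (n == 1) return(rec_xyz[1, ] + c(0, 0, r_min))
  step <- 0.25 * sigma
  margin <- 2 * sigma
  ax <- lapply(1:3, function(d)
    seq(min(rec_xyz[, d]) - margin, max(rec_xyz[, d]) + margin,
        by = step))
  pts <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  dimnames(pts) <- NULL
  e <- numeric(nrow(pts))
  for (j in seq_len(n)) {
    r2 <- (pts[, 1] - rec_xyz[j, 1])^2 + (pts[, 2] - rec_xyz[j, 2])^2 +
      (pts[, 3] - rec_xyz[j, 3])^2
    s6 <- (sigma^2 / r2)^3
    e <- e + 4 * epsilon * (s6^2 - s6)
  }
  # polish the best grid candidates from distinct basins (jitter makes
  # competing sites nearly degenerate, so one polish is not enough)
  ord <- order(e)
  starts <- matrix(numeric(0), 0, 3)
  for (i in ord) {
    p <- pts[i, ]
    if (nrow(starts) == 0 ||
        min(rowSums(sweep(starts, 2, p)^2)) >= (0.3 * sigma)^2)
      starts <- rbind(starts, p)
    if (nrow(starts) >= 40) break
  }
  lj <- lj_pair_model(epsilon, sigma)
  frozen <- c(rep(TRUE, n), FALSE)
  best <- NULL
  best_e <- Inf
  for (k in seq_len(nrow(starts))) {
    fit <- cgbs_minimize(lj, rbind(rec_xyz, starts[k, ]), frozen,
                         control = cgbs_control(max_iterations = 500))
    if (fit$final_energy < best_e) {
      best_e <- fit$final_energy
      best <- fit$final_coords[n + 1, ]
    }
  }
  best
}

random_unit_vector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# Rodrigues rotation about a unit axis
rotation_matrix <- function(axis, angle) {
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Synthetic affinity screening table
#'
#' Generates a screening set that mimics an affinity-stratified compound
#' selection: Ki values are drawn log-uniformly within each of the four
#' [ki_tier()] tiers (tiers assigned in rotation so counts are balanced),
#' the experimental energy is `ki_to_energy(Ki)`, and the predicted score
#' is the experimental energy plus Gaussian noise of standard deviation
#' `noise_sigma`. Tier 4 is capped at the Ki of the -4 kcal/mol
#' weak-binder cutoff (about 1.2 mM) so every generated compound survives
#' [select_compounds()] with default settings.
#'
#' @param n number of compounds (>= 4).
#' @param noise_sigma predicted-score noise, kcal/mol.
#' @param seed integer seed.
#' @param temperature temperature for the Ki conversion, Kelvin.
#' @return data.frame with columns `compound_id, Ki, elements, tier,
#'   experimental_energy, predicted_score`.
#' @export
make_screening_table <- function(n, noise_sigma = 1, seed = 1L,
                                 temperature = 298.15) {
  stopifnot(n >= 4, noise_sigma >= 0)
  lo <- c(1e-11, 1e-8, 1e-6, 1e-4)
  hi <- c(1e-8, 1e-6, 1e-4, energy_to_ki(-4, temperature))
  tier <- rep_len(1:4, n)
  withr::with_seed(seed, {
    Ki <- 10^stats::runif(n, log10(lo[tier]), log10(hi[tier]))
    energy <- ki_to_energy(Ki, temperature)
    data.frame(
      compound_id = sprintf("cmpd_%04d", seq_len(n)),
      Ki = Ki,
      elements = "C H O N",
      tier = tier,
      experimental_energy = energy,
      predicted_score = energy + stats::rnorm(n, 0, noise_sigma),
      stringsAsFactors = FALSE)
  })
}
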