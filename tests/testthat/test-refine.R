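# small helper: receptor atoms strung along x, one residue per atom
line_receptor <- function(xs) {
  structure3d(rep("C", length(xs)), cbind(xs, 0, 0),
              residue_name = "REC", residue_id = seq_along(xs),
              chain_id = "R")
}

test_that("truncation keeps whole residues inside the radius", {
  rec <- structure3d(rep("C", 4), rbind(c(0, 0, 0), c(25, 0, 0),
                                        c(11.9, 0, 0), c(13.5, 0, 0)),
                     residue_id = c(1L, 2L, 3L, 3L), chain_id = "A",
                     atom_name = c("CA", "CA", "CA", "CB"))
  lig <- structure3d("C", rbind(c(0, 0, 0)))
  pocket <- truncate_receptor(rec, lig, radius = 12)
  # residue 2 (25 A away) is dropped; residue 3 is kept whole because one
  # of its atoms is at 11.9 A even though the other is beyond the radius
  expect_setequal(unique(pocket$atoms$residue_id), c(1L, 3L))
  expect_equal(sum(pocket$atoms$residue_id == 3L), 2)
  expect_warning(truncate_receptor(rec, lig, radius = 5), "8-15")
  far_lig <- structure3d("C", rbind(c(1000, 0, 0)))
  expect_error(truncate_receptor(rec, far_lig, radius = 12), "no residue")
})

test_that("truncation is invariant under a rigid shift of the system", {
  withr::with_seed(21, {
    rec <- structure3d(rep("C", 12), random_lattice_coords(12) * 4,
                       residue_id = rep(1:4, each = 3), chain_id = "A")
  })
  lig <- structure3d("C", rbind(c(3, 3, 3)))
  p1 <- suppressWarnings(truncate_receptor(rec, lig, radius = 8))
  shift <- c(7.7, -3.1, 12.9)
  rec2 <- set_coords(rec, sweep(get_coords(rec), 2, shift, "+"))
  lig2 <- set_coords(lig, get_coords(lig) + shift)
  p2 <- suppressWarnings(truncate_receptor(rec2, lig2, radius = 8))
  expect_identical(p1$atoms$residue_id, p2$atoms$residue_id)
})

test_that("severed backbone bonds are hydrogen-capped at 1.09 A", {
  bb <- structure3d(rep(c("N", "C", "C", "O"), 3),
                    rbind(c(0, 0, 0), c(1.4, 0, 0), c(2.8, 0, 0),
                          c(2.8, 1.2, 0),
                          c(4.2, 0, 0), c(5.6, 0, 0), c(7.0, 0, 0),
                          c(7.0, 1.2, 0),
                          c(8.4, 0, 0), c(9.8, 0, 0), c(11.2, 0, 0),
                          c(11.2, 1.2, 0)),
                    residue_name = "ALA", residue_id = rep(1:3, each = 4),
                    chain_id = "A",
                    atom_name = rep(c("N", "CA", "C", "O"), 3))
  lig <- structure3d("C", rbind(c(0, 3, 0)))
  pocket <- suppressWarnings(truncate_receptor(bb, lig, radius = 8))
  # residues 1-2 kept, residue 3 dropped, one H cap on residue 2's C
  caps <- pocket$atoms[pocket$atoms$element == "H", ]
  expect_equal(nrow(caps), 1)
  expect_equal(caps$residue_id, 2L)
  cpos <- get_coords(pocket)[trimws(pocket$atoms$atom_name) == "C" &
                               pocket$atoms$residue_id == 2L, ]
  expect_equal(sqrt(sum((c(caps$x, caps$y, caps$z) - cpos)^2)), 1.09,
               tolerance = 1e-9)
})

test_that("region assignment splits at the boundary, inclusively", {
  rec <- line_receptor(c(2.0, 2.5, 3.0))
  lig <- structure3d("C", rbind(c(0, 0, 0)))
  asg <- assign_regions(rec, lig, boundary = 2.5)
  expect_identical(asg$active_indices, c(1L, 2L))   # 2.0 and exactly 2.5
  expect_identical(asg$frozen_indices, 3L)          # 3.0 A -> frozen
  expect_equal(asg$weights, c(5, 5, -1))
  expect_equal(asg$reference_coords, get_coords(rec))
  # frozen and active partition the receptor
  expect_setequal(c(asg$active_indices, asg$frozen_indices), 1:3)
  stamped <- apply_region_weights(rec, asg)
  expect_equal(stamped$atoms$restraint_weight, c(5, 5, -1))
})

test_that("binding energy is the complex minus component energies", {
  expect_equal(binding_energy(-10, -6, -3), -1)
  expect_equal(binding_energy(-7.25, -7.25, 0), 0)
  expect_error(binding_energy(NA, 0, 0), "finite")
  expect_error(binding_energy(Inf, 0, 0), "finite")
})

test_that("refining an LJ dimer toy recovers the well depth", {
  # frozen 1-atom receptor, free 1-atom ligand starting at 1.5 sigma
  rec <- structure3d("C", rbind(c(0, 0, 0)), chain_id = "R")
  lig <- structure3d("C", rbind(c(0, 0, 1.5)), chain_id = "L")
  asg <- assign_regions(rec, lig, boundary = 0.5)  # receptor frozen
  expect_length(asg$frozen_indices, 1)
  out <- refine_pose(rec, lig, asg, lj_pair_model(1, 1))
  expect_true(out$score$converged)
  # single-atom receptor and ligand have zero self-energy
  expect_equal(out$score$E_rec, 0)
  expect_equal(out$score$E_lig, 0)
  expect_equal(out$score$delta_E_bind, -1, tolerance = 1e-3)
  # frozen pocket coordinates identical to input
  expect_identical(get_coords(out$structure)[1, ], c(0, 0, 0))
})

test_that("non-interacting partitions give exactly zero binding energy", {
  toy <- make_toy_complex(4, 2, seed = 2)
  asg <- assign_regions(toy$receptor, toy$ligand)
  # cutoff below every receptor-ligand cross distance: no interaction
  m <- lj_pair_model(1, 1, cutoff = 0.9)
  out <- refine_pose(toy$receptor, toy$ligand, asg, m,
                     control = cgbs_control(max_iterations = 50))
  expect_equal(out$score$delta_E_bind, 0, tolerance = 1e-10)
})

test_that("dEbind equals the summed cross-interaction terms for a pairwise model", {
  toy <- make_toy_complex(6, 2, seed = 3)
  asg <- assign_regions(toy$receptor, toy$ligand)
  out <- refine_pose(toy$receptor, toy$ligand, asg, lj_pair_model(1, 1),
                     control = cgbs_control(max_iterations = 200))
  xc <- get_coords(out$structure)
  np <- n_atoms(toy$receptor)
  cross <- 0
  for (i in seq_len(np)) {
    for (j in seq.int(np + 1, nrow(xc))) {
      r2 <- sum((xc[i, ] - xc[j, ])^2)
      s6 <- (1 / r2)^3
      cross <- cross + 4 * (s6^2 - s6)
    }
  }
  expect_equal(out$score$delta_E_bind, cross, tolerance = 1e-8)
})

test_that("refinement never increases the complex energy", {
  toy <- make_toy_complex(8, 2, seed = 5)
  asg <- assign_regions(toy$receptor, toy$ligand)
  m <- lj_pair_model(1, 1)
  start <- combine_structures(toy$receptor, toy$ligand)
  # perturbed start so there is something to relax
  start <- set_coords(start, get_coords(start) +
                        withr::with_seed(9, matrix(stats::runif(
                          3 * n_atoms(start), -0.05, 0.05),
                          n_atoms(start), 3)))
  pose <- subset_atoms(start, seq.int(n_atoms(toy$receptor) + 1,
                                      n_atoms(start)))
  pocket <- subset_atoms(start, seq_len(n_atoms(toy$receptor)))
  asg2 <- assign_regions(pocket, pose)
  out <- refine_pose(pocket, pose, asg2, m,
                     control = cgbs_control(max_iterations = 300))
  e_start <- m$eval(get_coords(start))$energy
  e_end <- m$eval(get_coords(out$structure))$energy
  expect_lte(e_end, e_start)
})

test_that("pose ranking is ascending in dEbind and stable on ties", {
  sc <- data.frame(pose_id = c("a", "b", "c"),
                   delta_E_bind = c(-5, -9, -1))
  expect_equal(rank_poses(sc)$rank, c(2L, 1L, 3L))
  tied <- data.frame(pose_id = letters[1:4], delta_E_bind = rep(-2, 4))
  expect_equal(rank_poses(tied)$rank, 1:4)   # input order preserved
  withr::with_seed(13, e <- stats::rnorm(10))
  got <- rank_poses(data.frame(pose_id = paste0("p", 1:10),
                               delta_E_bind = e))$rank
  expect_identical(sort(got), 1:10)
  expect_identical(got, rank(e, ties.method = "first"))  # brute-force sort
  expect_error(rank_poses(data.frame(delta_E_bind = numeric(0))), "nrow")
})
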