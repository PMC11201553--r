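make_complex <- function(seed = 1, n_rec = 8, n_lig = 3) {
  withr::with_seed(seed, {
    rec <- random_lattice_coords(n_rec, spacing = 2)
    lig <- sweep(random_lattice_coords(n_lig), 2, c(1, 1, 4), "+")
  })
  structure3d(c(rep("C", n_rec), rep(c("C", "O", "H"),
                                     length.out = n_lig)),
              rbind(rec, lig), chain_id = rep(c("R", "L"),
                                              c(n_rec, n_lig)))
}

test_that("receptor-anchored RMSD removes joint rigid motion only", {
  cx <- make_complex(1)
  lig_idx <- 9:11
  expect_equal(receptor_anchored_rmsd(cx, cx, lig_idx), 0)
  # joint rigid transform of the whole predicted complex: RMSD 0
  ax <- c(1, 2, -1); ax <- ax / sqrt(sum(ax^2))
  R <- cgbsdock:::rotation_matrix(ax, 0.8)
  moved <- set_coords(cx, sweep(get_coords(cx) %*% t(R), 2,
                                c(5, -3, 2), "+"))
  expect_lt(receptor_anchored_rmsd(cx, moved, lig_idx), 1e-8)
  # pure in-pocket ligand translation is fully retained
  xc <- get_coords(cx)
  xc[lig_idx, 1] <- xc[lig_idx, 1] + 1
  expect_equal(receptor_anchored_rmsd(cx, set_coords(cx, xc), lig_idx), 1,
               tolerance = 1e-8)
  # ... even when the whole system is also rigidly moved afterwards
  moved2 <- set_coords(cx, sweep(xc %*% t(R), 2, c(-2, 7, 1), "+"))
  expect_equal(receptor_anchored_rmsd(cx, moved2, lig_idx), 1,
               tolerance = 1e-8)
})

test_that("RMSD uses ligand heavy atoms and validates its inputs", {
  cx <- make_complex(2)
  lig_idx <- 9:11                         # elements C, O, H
  xc <- get_coords(cx)
  xc[11, ] <- xc[11, ] + 5                # move only the ligand hydrogen
  expect_equal(receptor_anchored_rmsd(cx, set_coords(cx, xc), lig_idx), 0,
               tolerance = 1e-8)
  expect_gt(receptor_anchored_rmsd(cx, set_coords(cx, xc), lig_idx,
                                   heavy_only = FALSE), 1)
  small <- structure3d(rep("C", 3), rbind(c(0, 0, 0), c(1, 0, 0),
                                          c(0, 1, 0)))
  expect_error(receptor_anchored_rmsd(small, small, 2:3), "at least 3")
  expect_error(receptor_anchored_rmsd(cx, make_complex(2, n_rec = 7),
                                      9:11), "matching atom counts")
})

test_that("top-category minima, first category and success follow the ranks", {
  s <- top_category_minima(c(3, 2, 1, 4, 4, 4, 4, 4, 4, 4))
  expect_equal(unname(s$minima), c(3, 1, 1, 1))
  expect_equal(s$first_category, 3L)
  expect_true(s$success)
  dec <- top_category_minima(seq(10, 1))  # strictly decreasing
  expect_equal(dec$first_category, 10L)
  expect_false(dec$success)
  const <- top_category_minima(rep(2.5, 10))
  expect_equal(unname(const$minima), rep(2.5, 4))
  expect_equal(const$first_category, 1L)
  expect_error(top_category_minima(numeric(0)))
  short <- top_category_minima(c(2, 1))   # capped categories
  expect_equal(unname(short$minima), rep(c(2, 1), c(1, 3)))
})

test_that("first_success_category matches published per-system quadruples", {
  r <- first_success_category(c(2.96, 0.92, 0.92, 0.92))
  expect_equal(r$category, 3L); expect_true(r$success)
  r <- first_success_category(c(0.47, 0.47, 0.47, 0.47))
  expect_equal(r$category, 1L); expect_true(r$success)
  r <- first_success_category(c(8.55, 8.27, 1.47, 1.07))
  expect_equal(r$category, 10L); expect_false(r$success)
  expect_error(first_success_category(c(1, 2, 3, 4)), "non-increasing")
})

test_that("success rates aggregate as weighted means over subsets", {
  mk <- function(success) structure(list(success = success),
                                    class = "top_category_summary")
  a <- lapply(c(TRUE, TRUE, FALSE), mk)
  b <- lapply(c(TRUE, FALSE, FALSE, FALSE, TRUE), mk)
  ra <- success_rate(a); rb <- success_rate(b)
  rall <- success_rate(c(a, b))
  expect_equal(rall$percent,
               (ra$percent * ra$n + rb$percent * rb$n) / (ra$n + rb$n))
  expect_equal(success_rate(list(mk(TRUE)))$percent, 100)
  counts <- category_occurrence_counts(lapply(c(1, 1, 3, 10), function(k)
    structure(list(first_category = k), class = "top_category_summary")))
  expect_equal(unname(counts), c(2L, 1L, 0L, 1L))
  expect_equal(sum(counts), 4L)
})

test_that("pearson and spearman match brute-force oracles", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  y <- c(2, 1, 4, 3, 5)
  expect_equal(pearson_r(x, y), brute_pearson(x, y), tolerance = 1e-12)
  expect_equal(spearman_rho(x, exp(x)), 1)          # monotone transform
  expect_equal(spearman_rho(x, rev(x)), -1)
  ytied <- c(2, 2, 4, 3, 5)
  expect_equal(spearman_rho(x, ytied), brute_spearman(x, ytied),
               tolerance = 1e-12)
  withr::with_seed(31, {
    u <- stats::rnorm(20)
    v <- stats::rnorm(20) + 0.5 * u
  })
  expect_equal(pearson_r(u, v), brute_pearson(u, v), tolerance = 1e-12)
  expect_equal(spearman_rho(u, v), brute_spearman(u, v), tolerance = 1e-12)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "zero-variance")
  expect_error(spearman_rho(c(1, 1, 1), c(1, 2, 3)), "tied")
  expect_error(pearson_r(1:3, 1:4), "equal length")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("spearman is invariant under strictly monotone transforms", {
  withr::with_seed(17, {
    x <- stats::rnorm(30)
    y <- stats::rnorm(30)
  })
  base <- spearman_rho(x, y)
  expect_equal(spearman_rho(exp(x), y), base, tolerance = 1e-12)
  expect_equal(spearman_rho(x, y^3 + 5 * y), base, tolerance = 1e-12)
})

test_that("Ki converts to binding free energy via RT ln Ki", {
  expect_equal(ki_to_energy(1), 0)
  expect_equal(ki_to_energy(1e-9), -12.28, tolerance = 0.01 / 12.28)
  expect_equal(ki_to_energy(1e-9),
               1.98720425864e-3 * 298.15 * log(1e-9), tolerance = 1e-12)
  # the -4 kcal/mol cutoff corresponds to Ki ~ 1.17e-3 M
  expect_equal(energy_to_ki(-4), 1.17e-3, tolerance = 0.01)
  expect_equal(ki_to_energy(energy_to_ki(-4)), -4, tolerance = 1e-12)
  expect_error(ki_to_energy(0), "positive")
  expect_error(ki_to_energy(-1e-9), "positive")
  expect_equal(ki_tier(c(5e-9, 1e-8, 5e-7, 2e-5, 3e-4)),
               c(1L, 2L, 2L, 3L, 4L))
})

test_that("compound selection filters elements, affinity and tier caps", {
  rec <- data.frame(
    compound_id = sprintf("c%d", 1:6),
    Ki = c(5e-9, 2e-7, 3e-5, 5e-4, energy_to_ki(-3.5), 1e-9),
    elements = c("C H O N", "C H Br", "C H S Cl", "C H O", "C H O",
                 "C H F"),
    stringsAsFactors = FALSE)
  out <- select_compounds(rec, seed = 1)
  expect_false("c2" %in% out$compound_id)   # Br excluded
  expect_false("c5" %in% out$compound_id)   # dG = -3.5 above the cutoff
  expect_true(all(c("c1", "c3", "c4", "c6") %in% out$compound_id))
  expect_equal(out$tier[out$compound_id == "c1"], 1L)  # Ki = 5 nM
  expect_equal(out$tier[out$compound_id == "c4"], 4L)
  # per-tier cap with a seeded subsample
  big <- data.frame(compound_id = sprintf("t%03d", 1:50),
                    Ki = rep(1e-9, 50), elements = "C H",
                    stringsAsFactors = FALSE)
  kept <- select_compounds(big, per_tier_cap = 10, seed = 7)
  expect_equal(nrow(kept), 10)
  expect_identical(kept$compound_id,
                   select_compounds(big, per_tier_cap = 10,
                                    seed = 7)$compound_id)
  kept2 <- select_compounds(big, per_tier_cap = 10, seed = 8)
  expect_false(identical(kept$compound_id, kept2$compound_id))
})

test_that("docking power summary reads a table like the shipped fixtures", {
  tab <- read_benchmark_table("docking_rmsd")
  expect_equal(nrow(tab), 46)
  expect_setequal(unique(tab$method), c("glide", "anicgbs"))
  one <- docking_power_summary(tab[tab$method == "glide", ][1:4, ])
  expect_equal(sum(one$counts), 4L)
})
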