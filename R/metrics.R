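#' Receptor-anchored ligand RMSD
#'
#' The docking-power RMSD: the least-squares rigid superposition
#' (Kabsch) is computed on the receptor atoms only, the resulting
#' transform is applied to the whole predicted complex, and the RMSD is
#' then taken over the ligand heavy atoms with no further fitting.
#' Because the ligand is never fitted to itself, translation and rotation
#' of the ligand within the binding pocket contribute fully to the value.
#'
#' @param reference_complex reference (crystal) complex `structure3d`.
#' @param predicted_complex predicted complex with the same atoms in the
#'   same order.
#' @param ligand_selection logical or integer atom index of the ligand
#'   atoms within both complexes; all remaining atoms are the receptor
#'   anchor.
#' @param heavy_only drop hydrogens from the ligand RMSD (default TRUE).
#' @return RMSD in Angstrom.
#' @export
receptor_anchored_rmsd <- function(reference_complex, predicted_complex,
                                   ligand_selection, heavy_only = TRUE) {
  stopifnot(inherits(reference_complex, "structure3d"),
            inherits(predicted_complex, "structure3d"))
  n <- n_atoms(reference_complex)
  if (n_atoms(predicted_complex) != n)
    stop("reference and predicted complexes must have matching atom counts")
  lig <- rep(FALSE, n)
  lig[ligand_selection] <- TRUE
  if (!any(lig) || all(lig))
    stop("ligand selection must pick a proper subset of the atoms")
  rec <- which(!lig)
  if (length(rec) < 3)
    stop("receptor anchor needs at least 3 atoms for superposition")
  ref <- get_coords(reference_complex)
  prd <- get_coords(predicted_complex)
  moved <- bio3d::fit.xyz(as.vector(t(ref)), as.vector(t(prd)),
                          fixed.inds = bio3d::atom2xyz(rec),
                          mobile.inds = bio3d::atom2xyz(rec))
  prd_fit <- matrix(moved, ncol = 3, byrow = TRUE)
  keep <- which(lig)
  if (heavy_only) {
    hv <- heavy_atoms(reference_complex)[keep]
    if (!any(hv)) stop("ligand has no heavy atoms")
    keep <- keep[hv]
  }
  sqrt(mean(rowSums((prd_fit[keep, , drop = FALSE] -
                       ref[keep, , drop = FALSE])^2)))
}

#' Lowest RMSD within the Top-1/3/5/10 rank categories
#'
#' Given the RMSD of each ranked pose (rank 1 first), reports the lowest
#' RMSD found within the top 1, top 3, top 5 and top 10 poses, the first
#' (smallest) category whose minimum already equals the overall top-10
#' minimum, and whether that category is within the top three (the
#' "success" criterion of docking-power analysis). With fewer than 10
#' poses the categories are capped at the pose count.
#'
#' @param ranked_rmsds numeric RMSDs in rank order (rank 1 first),
#'   normally 10 values.
#' @param tolerance equality tolerance passed to
#'   [first_success_category()].
#' @return an object of class `top_category_summary`: list with `minima`
#'   (named length-4), `first_category` and `success`.
#' @export
top_category_minima <- function(ranked_rmsds, tolerance = 1e-9) {
  stopifnot(is.numeric(ranked_rmsds), length(ranked_rmsds) >= 1,
            all(is.finite(ranked_rmsds)))
  if (length(ranked_rmsds) > 10)
    stop("at most 10 ranked poses expected")
  n <- length(ranked_rmsds)
  minima <- vapply(c(1, 3, 5, 10), function(k)
    min(ranked_rmsds[seq_len(min(k, n))]), numeric(1))
  names(minima) <- c("top1", "top3", "top5", "top10")
  fc <- first_success_category(minima, tolerance)
  structure(list(minima = minima, first_category = fc$category,
                 success = fc$success),
            class = "top_category_summary")
}

#' @export
print.top_category_summary <- function(x, ...) {
  cat(sprintf(
    "top-category minima (A): %s; first category Top %d (%s)\n",
    paste(sprintf("%s=%.2f", names(x$minima), x$minima), collapse = " "),
    x$first_category, if (x$success) "success" else "no success"))
  invisible(x)
}

#' First rank category attaining the overall minimum RMSD
#'
#' @param minima non-increasing length-4 vector: lowest RMSD within the
#'   Top 1, 3, 5 and 10 poses.
#' @param tolerance equality tolerance on RMSD values (1e-9 for raw
#'   values; use 0 only for exact table readbacks).
#' @return `list(category, success)` where `category` is the smallest N
#'   in {1, 3, 5, 10} whose minimum matches the Top-10 minimum and
#'   `success` is `category <= 3`.
#' @export
first_success_category <- function(minima, tolerance = 1e-9) {
  stopifnot(is.numeric(minima), length(minima) == 4,
            all(is.finite(minima)))
  if (any(diff(minima) > tolerance))
    stop("category minima must be non-increasing")
  cats <- c(1L, 3L, 5L, 10L)
  hit <- which(minima - minima[4] <= tolerance)
  category <- cats[min(hit)]
  list(category = category, success = category <= 3L)
}

#' Top-rank identification success rate
#'
#' Fraction of systems whose native-like pose (the lowest-RMSD pose among
#' the top 10) already occurs within the top three ranked poses.
#'
#' @param summaries list of [top_category_minima()] results (or any
#'   objects with a logical `success` component).
#' @return `list(n, n_success, percent, percent_rounded)`; `percent` is
#'   unrounded, `percent_rounded` is the nearest integer used for
#'   reporting.
#' @export
success_rate <- function(summaries) {
  stopifnot(length(summaries) >= 1)
  succ <- vapply(summaries, function(s) isTRUE(s$success), logical(1))
  pct <- 100 * mean(succ)
  list(n = length(succ), n_success = sum(succ), percent = pct,
       percent_rounded = round(pct))
}

#' Histogram of first-success categories
#'
#' @param summaries list of [top_category_minima()] results.
#' @return named integer vector of counts over the categories
#'   `c("1", "3", "5", "10")`; the counts sum to the number of systems.
#' @export
category_occurrence_counts <- function(summaries) {
  fc <- vapply(summaries, function(s) as.integer(s$first_category),
               integer(1))
  counts <- vapply(c(1L, 3L, 5L, 10L), function(k) sum(fc == k),
                   integer(1))
  names(counts) <- c("1", "3", "5", "10")
  counts
}

#' Docking-power summary of an RMSD table
#'
#' Convenience wrapper: one row per system with the Top-1/3/5/10 lowest
#' RMSDs of one method, as printed in docking-power tables.
#'
#' @param tab data.frame with numeric columns `top1, top3, top5, top10`.
#' @param tolerance equality tolerance; defaults to 0 (exact match on
#'   table readbacks printed to fixed precision).
#' @return `list(summaries, counts, success)`: the per-system summaries,
#'   the category occurrence counts and the [success_rate()] result.
#' @export
docking_power_summary <- function(tab, tolerance = 0) {
  need <- c("top1", "top3", "top5", "top10")
  stopifnot(is.data.frame(tab), all(need %in% names(tab)))
  summaries <- lapply(seq_len(nrow(tab)), function(i) {
    minima <- as.numeric(tab[i, need])
    fc <- first_success_category(minima, tolerance)
    structure(list(minima = minima, first_category = fc$category,
                   success = fc$success),
              class = "top_category_summary")
  })
  list(summaries = summaries,
       counts = category_occurrence_counts(summaries),
       success = success_rate(summaries))
}

#' Pearson and Spearman correlation
#'
#' `pearson_r` is the product-moment correlation used for scoring-power
#' evaluation; `spearman_rho` computes Pearson on fractional (average)
#' ranks and is used for ranking power. Both require at least 3 paired
#' observations and error on zero-variance input.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return the correlation coefficient in [-1, 1].
#' @export
pearson_r <- function(x, y) {
  check_corr_input(x, y)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for zero-variance input")
  stats::cor(x, y, method = "pearson")
}

#' @rdname pearson_r
#' @export
spearman_rho <- function(x, y) {
  check_corr_input(x, y)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("rank correlation undefined when a variable is entirely tied")
  stats::cor(rx, ry, method = "pearson")
}

check_corr_input <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length")
  if (length(x) < 3)
    stop("correlation needs at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite values in correlation input")
  invisible(TRUE)
}

#' Convert an inhibition constant to a binding free energy
#'
#' \deqn{\Delta G = RT \ln K_i} with Ki in molar (referenced to 1 M) and
#' R = 1.98720425864e-3 kcal/mol/K. A Ki of 1 nM at 298.15 K gives about
#' -12.28 kcal/mol; the -4 kcal/mol weak-binder cutoff corresponds to
#' Ki of roughly 1.2 mM.
#'
#' @param Ki inhibition (or dissociation) constant, molar; must be > 0.
#' @param temperature temperature in Kelvin (default 298.15).
#' @return binding free energy, kcal/mol.
#' @export
ki_to_energy <- function(Ki, temperature = 298.15) {
  if (any(!is.finite(Ki)) || any(Ki <= 0))
    stop("Ki must be positive and finite")
  phys_constants$gas_constant_R * temperature * log(Ki)
}

#' @rdname ki_to_energy
#' @param energy binding free energy in kcal/mol (inverse conversion).
#' @export
energy_to_ki <- function(energy, temperature = 298.15) {
  exp(energy / (phys_constants$gas_constant_R * temperature))
}

#' Affinity tier of an inhibition constant
#'
#' The four tiers used for screening-set construction: (1) Ki < 10 nM,
#' (2) 10 nM <= Ki < 1 uM, (3) 1 uM <= Ki < 100 uM, (4) Ki >= 100 uM.
#'
#' @param Ki inhibition constant(s), molar.
#' @return integer tier(s) in 1..4.
#' @export
ki_tier <- function(Ki) {
  stopifnot(all(Ki > 0))
  findInterval(Ki, c(1e-8, 1e-6, 1e-4)) + 1L
}

#' Filter and subsample a screening compound set
#'
#' Applies the compound-selection rules used to build affinity-stratified
#' screening sets: drop compounds containing elements outside the allowed
#' set (ANI-2x-compatible organics by default), drop very weak binders
#' whose converted binding energy lies above `energy_cutoff`, stratify
#' the survivors into the four [ki_tier()] affinity tiers, and keep at
#' most `per_tier_cap` compounds per tier (a seeded uniform subsample
#' when a tier is over the cap).
#'
#' @param records data.frame with columns `compound_id`, `Ki` (molar) and
#'   `elements` (character: element symbols separated by spaces and/or
#'   commas).
#' @param per_tier_cap maximum compounds kept per tier (default 300).
#' @param energy_cutoff weak-binder cutoff in kcal/mol (default -4);
#'   compounds with `ki_to_energy(Ki) > energy_cutoff` are dropped.
#' @param allowed_elements permitted element symbols.
#' @param seed integer seed for the per-tier subsample.
#' @return the filtered data.frame with added columns
#'   `experimental_energy` and `tier`; possibly empty.
#' @export
select_compounds <- function(records, per_tier_cap = 300,
                             energy_cutoff = -4,
                             allowed_elements = c("C", "H", "O", "N",
                                                  "S", "F", "Cl"),
                             seed = 1L) {
  stopifnot(is.data.frame(records),
            all(c("compound_id", "Ki", "elements") %in% names(records)))
  allowed <- toupper(allowed_elements)
  el_ok <- vapply(records$elements, function(e) {
    syms <- toupper(strsplit(trimws(e), "[,[:space:]]+")[[1]])
    all(syms %in% allowed)
  }, logical(1), USE.NAMES = FALSE)
  out <- records[el_ok & records$Ki > 0, , drop = FALSE]
  if (nrow(out) == 0) return(annotate_tiers(out))
  out$experimental_energy <- ki_to_energy(out$Ki)
  out <- out[out$experimental_energy <= energy_cutoff, , drop = FALSE]
  out <- annotate_tiers(out)
  if (nrow(out) == 0) return(out)
  keep <- withr::with_seed(seed, unlist(lapply(1:4, function(tr) {
    idx <- which(out$tier == tr)
    if (length(idx) > per_tier_cap) sort(sample(idx, per_tier_cap))
    else idx
  })))
  out <- out[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

annotate_tiers <- function(df) {
  if (!"experimental_energy" %in% names(df))
    df$experimental_energy <- numeric(nrow(df))
  df$tier <- if (nrow(df)) ki_tier(df$Ki) else integer(0)
  df
}
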