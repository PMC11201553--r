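#' Published docking-benchmark tables
#'
#' The package ships, as plain TSV fixtures, the printed per-system
#' results of the 23-system docking-power benchmark (lowest ligand RMSD
#' within the Top-1/3/5/10 ranked poses, for Glide docking and for
#' CG-BS rescoring with the ANI-2x potential) and the 11-system
#' scoring/ranking-power benchmarks (per-system Pearson R and Spearman
#' rho for both methods). They are the worked-example inputs for the
#' evaluation layer: feeding the RMSD quadruples through
#' [docking_power_summary()] reproduces the published success rates and
#' category counts, and column means of the correlation tables reproduce
#' the published averages.
#'
#' @param which one of `"docking_rmsd"` (columns `system, method, top1,
#'   top3, top5, top10`; method is `"glide"` or `"anicgbs"`),
#'   `"scoring_pearson"` or `"ranking_spearman"` (columns `system,
#'   glide, anicgbs`).
#' @return a data.frame.
#' @export
read_benchmark_table <- function(which = c("docking_rmsd",
                                           "scoring_pearson",
                                           "ranking_spearman")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0(which, "_table.tsv"),
                      package = "cgbsdock", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
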