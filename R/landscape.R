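#' Relative m6A level: Z-score of the Wald statistic within a population
#'
#' The relative m6A level of a gene in a cell population is the Z-score of
#' its IP-vs-INPUT Wald statistic across all scored genes of that
#' population.  The population SD (divisor n) is used so the symmetric-pair
#' case maps exactly to +/-1 and the normalization identity (mean 0, SD 1)
#' is exact.
#'
#' @param results an `enrichment_result` for one population (or a numeric
#'   vector of Wald statistics).
#' @return named numeric vector of Z-scores.
#' @export
relative_m6a_zscore <- function(results) {
  if (is.data.frame(results)) {
    w <- stats::setNames(results$wald_stat, results$gene)
  } else {
    w <- results
  }
  if (length(w) < 2) stop("relative_m6a_zscore: need >= 2 scored genes")
  s <- stats::sd(w) * sqrt((length(w) - 1) / length(w))
  if (s == 0) stop("relative_m6a_zscore: Wald statistics are constant; Z undefined")
  (w - mean(w)) / s
}

#' Call high-confidence m6A targets
#'
#' A gene is a target when log2 fold change exceeds `lfc_thresh` AND the
#' raw Wald p-value is below `p_thresh`, both strictly.  Defaults are the
#' standard gene-level cutoff log2FC > 1 and P < 0.05; the raw (not
#' BH-adjusted) p-value is used by default, with adjusted values available
#' via [benjamini_hochberg()] for users who prefer FDR control.
#'
#' @param results an `enrichment_result`.
#' @param lfc_thresh log2 fold-change cutoff (> 0).
#' @param p_thresh p-value cutoff in (0, 1].
#' @return named logical vector over the scored genes.
#' @export
call_targets <- function(results, lfc_thresh = 1, p_thresh = 0.05) {
  if (lfc_thresh <= 0) stop("call_targets: lfc_thresh must be positive")
  if (p_thresh <= 0 || p_thresh > 1) stop("call_targets: p_thresh must be in (0, 1]")
  stats::setNames(results$log2fc > lfc_thresh & results$p_value < p_thresh,
                  results$gene)
}

#' Assemble per-population enrichment results into an m6A landscape
#'
#' Aligns gene universes across populations (union); genes unscored in a
#' population (e.g. filtered for low counts) are missing (NA) there — in
#' both the Z and the target channel — and are excluded from that
#' population's Z normalization, so absent genes never deflate the SD or
#' masquerade as "not enriched".
#'
#' @param results_by_pop named list of `enrichment_result` data.frames,
#'   one per population; names are population ids (order preserved).
#' @param lfc_thresh,p_thresh target-calling thresholds, see
#'   [call_targets()].
#' @return object of class `m6a_landscape`: list with `populations`,
#'   `genes`, `z` (gene x population matrix, NA = unscored), `is_target`
#'   (logical matrix, NA = unscored), `thresholds`.
#' @export
assemble_landscape <- function(results_by_pop, lfc_thresh = 1, p_thresh = 0.05) {
  if (length(results_by_pop) < 1) stop("assemble_landscape: need >= 1 population")
  pops <- names(results_by_pop)
  if (is.null(pops) || any(pops == ""))
    stop("assemble_landscape: results must be named by population")
  if (anyDuplicated(pops))
    stop("assemble_landscape: duplicated population: ",
         pops[duplicated(pops)][1])
  genes <- sort(unique(unlist(lapply(results_by_pop, function(r) r$gene))))
  z <- matrix(NA_real_, length(genes), length(pops),
              dimnames = list(genes, pops))
  tgt <- matrix(NA, length(genes), length(pops),
                dimnames = list(genes, pops))
  for (pop in pops) {
    r <- results_by_pop[[pop]]
    z[r$gene, pop] <- relative_m6a_zscore(r)
    tgt[r$gene, pop] <- call_targets(r, lfc_thresh, p_thresh)
  }
  structure(list(populations = pops, genes = genes, z = z, is_target = tgt,
                 thresholds = list(lfc_thresh = lfc_thresh,
                                   p_thresh = p_thresh)),
            class = "m6a_landscape")
}

#' @export
print.m6a_landscape <- function(x, ...) {
  cat(sprintf("m6a_landscape: %d genes x %d populations, %d union targets\n",
              length(x$genes), length(x$populations), union_target_count(x)))
  invisible(x)
}

#' Number of genes that are a target in at least one population
#' @param landscape an [assemble_landscape()] result.
#' @return integer count of union targets.
#' @export
union_target_count <- function(landscape) {
  stopifnot(inherits(landscape, "m6a_landscape"))
  sum(rowSums(landscape$is_target, na.rm = TRUE) > 0)
}

#' Genes that are a target in at least one population
#' @param landscape an [assemble_landscape()] result.
#' @return character vector of gene ids.
#' @export
union_targets <- function(landscape) {
  stopifnot(inherits(landscape, "m6a_landscape"))
  landscape$genes[rowSums(landscape$is_target, na.rm = TRUE) > 0]
}

#' Mean-center gene profiles across populations
#'
#' Subtracts from each gene row its cross-population mean; used for
#' dot-plot style displays where m6A and expression levels are shown
#' relative to the mean of the populations.  Idempotent.
#'
#' @param profiles gene x population numeric matrix (complete rows).
#' @return matrix of the same shape with zero row means.
#' @export
mean_center_profiles <- function(profiles) {
  profiles <- as.matrix(profiles)
  sweep(profiles, 1, rowMeans(profiles), "-")
}

#' Flatten a landscape to a long table
#' @param landscape an [assemble_landscape()] result.
#' @return data.frame gene, population, z, is_target (NA rows for unscored
#'   cells are kept so the table round-trips the landscape).
#' @export
landscape_table <- function(landscape) {
  stopifnot(inherits(landscape, "m6a_landscape"))
  data.frame(gene = rep(landscape$genes, length(landscape$populations)),
             population = rep(landscape$populations,
                              each = length(landscape$genes)),
             z = as.vector(landscape$z),
             is_target = as.vector(landscape$is_target),
             stringsAsFactors = FALSE)
}
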