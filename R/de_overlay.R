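#' Call differentially expressed genes from a KO-vs-WT contrast
#'
#' Direction is `up` when log2FC > `lfc_thresh` and p < `p_thresh`, `down`
#' symmetric, `ns` otherwise — strict inequalities, mirroring the m6A
#' target-calling convention.  The defaults are the standard |log2FC| >
#' 0.5, P < 0.05 expression cutoff (raw p by default).
#'
#' @param results an `enrichment_result` from [nb_wald_test()] with KO as
#'   numerator.
#' @param lfc_thresh absolute log2 fold-change cutoff (> 0).
#' @param p_thresh p-value cutoff in (0, 1].
#' @return data.frame of class `deg_table`: gene, log2fc, p_value,
#'   direction (up/down/ns).
#' @export
call_degs <- function(results, lfc_thresh = 0.5, p_thresh = 0.05) {
  if (lfc_thresh <= 0) stop("call_degs: lfc_thresh must be positive")
  if (p_thresh <= 0 || p_thresh > 1) stop("call_degs: p_thresh must be in (0, 1]")
  direction <- rep("ns", nrow(results))
  direction[results$log2fc > lfc_thresh & results$p_value < p_thresh] <- "up"
  direction[results$log2fc < -lfc_thresh & results$p_value < p_thresh] <- "down"
  out <- data.frame(gene = results$gene, log2fc = results$log2fc,
                    p_value = results$p_value, direction = direction,
                    stringsAsFactors = FALSE)
  class(out) <- c("deg_table", class(out))
  attr(out, "thresholds") <- list(lfc_thresh = lfc_thresh, p_thresh = p_thresh)
  out
}

#' Overlay m6A target status on a DEG table
#'
#' Tags each DEG with its m6A target status in the stated population —
#' by default the wild-type landscape of the contrasted population (target
#' status is defined in WT cells and overlaid on KO-vs-WT expression
#' changes).  Unscored (missing) landscape cells count as untagged.
#'
#' @param degs a [call_degs()] result.
#' @param landscape an [assemble_landscape()] result.
#' @param population population id whose target calls define tagging.
#' @return list with `table` (degs plus `m6a_tagged` column), `n_up_tagged`,
#'   `n_down_tagged`, `n_tagged`, `up_tagged`/`down_tagged` gene lists.
#' @export
overlay_m6a <- function(degs, landscape, population) {
  stopifnot(inherits(degs, "deg_table"), inherits(landscape, "m6a_landscape"))
  if (!population %in% landscape$populations)
    stop("overlay_m6a: population '", population, "' not in landscape")
  tgt <- landscape$is_target[, population]
  tagged <- degs$gene %in% names(tgt)[which(tgt)]
  tab <- degs
  tab$m6a_tagged <- tagged
  up_tagged <- tab$gene[tab$direction == "up" & tab$m6a_tagged]
  down_tagged <- tab$gene[tab$direction == "down" & tab$m6a_tagged]
  list(table = tab,
       n_up_tagged = length(up_tagged),
       n_down_tagged = length(down_tagged),
       n_tagged = length(up_tagged) + length(down_tagged),
       up_tagged = up_tagged, down_tagged = down_tagged)
}
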