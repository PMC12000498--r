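#' Classify each population's m6A targets as inherited or de novo
#'
#' Root targets are labelled `root_set`.  A non-root target is `inherited`
#' when the same gene is a target in the immediate parent (`mode =
#' "parent"`) or in any ancestor on the path to the root (`mode =
#' "any_ancestor"`, the default: a downstream population's relevant
#' upstream set spans the whole stem/progenitor chain); otherwise it is
#' `de_novo`.  A gene unscored (missing) in an ancestor counts as absent
#' there — inheritance requires positive evidence — and the evidence column
#' records the nearest upstream population carrying the target.
#'
#' @param landscape an [assemble_landscape()] result.
#' @param tree a [hierarchy_tree()]; every landscape population must be a
#'   node.
#' @param mode `"any_ancestor"` or `"parent"`.
#' @return data.frame of class `inheritance_table`: population, gene,
#'   origin (root_set/inherited/de_novo), evidence (nearest upstream
#'   carrier, "" otherwise); attribute `populations` preserves the
#'   landscape's population set for summaries.
#' @export
classify_inheritance <- function(landscape, tree,
                                 mode = c("any_ancestor", "parent")) {
  stopifnot(inherits(landscape, "m6a_landscape"),
            inherits(tree, "hierarchy_tree"))
  mode <- match.arg(mode)
  missing_pop <- setdiff(landscape$populations, tree$nodes)
  if (length(missing_pop))
    stop("classify_inheritance: population(s) not in tree: ",
         paste(missing_pop, collapse = ", "))
  tgt <- landscape$is_target
  is_tgt <- function(gene, pop) {
    if (!pop %in% colnames(tgt)) return(FALSE)  # population not assayed
    isTRUE(tgt[gene, pop])                      # NA (unscored) counts absent
  }
  rows <- list()
  for (pop in landscape$populations) {
    genes <- landscape$genes[which(tgt[, pop])]
    if (!length(genes)) next
    if (pop == tree$root) {
      rows[[pop]] <- data.frame(population = pop, gene = genes,
                                origin = "root_set", evidence = "",
                                stringsAsFactors = FALSE)
      next
    }
    anc <- tree_ancestors(tree, pop)
    if (mode == "parent") anc <- anc[1]
    origin <- character(length(genes))
    evidence <- character(length(genes))
    for (i in seq_along(genes)) {
      hit <- anc[vapply(anc, function(a) is_tgt(genes[i], a), TRUE)]
      if (length(hit)) {
        origin[i] <- "inherited"
        evidence[i] <- hit[1]  # nearest upstream carrier
      } else {
        origin[i] <- "de_novo"
        evidence[i] <- ""
      }
    }
    rows[[pop]] <- data.frame(population = pop, gene = genes, origin = origin,
                              evidence = evidence, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(population = character(0), gene = character(0),
               origin = character(0), evidence = character(0))
  rownames(out) <- NULL
  class(out) <- c("inheritance_table", class(out))
  attr(out, "populations") <- landscape$populations
  attr(out, "root") <- tree$root
  attr(out, "mode") <- mode
  out
}

#' Per-population origin fractions
#'
#' Fractions are over that population's targets.  The root reports
#' root_set fraction 1; a population with zero targets reports NA (not 0)
#' fractions — 0/0 is propagated honestly rather than silently zeroed.
#'
#' @param table an [classify_inheritance()] result.
#' @return data.frame population, n_targets, frac_root_set,
#'   frac_inherited, frac_de_novo.
#' @export
stage_fractions <- function(table) {
  stopifnot(inherits(table, "inheritance_table"))
  pops <- attr(table, "populations")
  out <- lapply(pops, function(pop) {
    sub <- table[table$population == pop, ]
    n <- nrow(sub)
    if (n == 0)
      return(data.frame(population = pop, n_targets = 0L,
                        frac_root_set = NA_real_, frac_inherited = NA_real_,
                        frac_de_novo = NA_real_))
    data.frame(population = pop, n_targets = n,
               frac_root_set = mean(sub$origin == "root_set"),
               frac_inherited = mean(sub$origin == "inherited"),
               frac_de_novo = mean(sub$origin == "de_novo"))
  })
  do.call(rbind, out)
}

#' Pooled origin fraction over a group of populations
#'
#' Pools all (population, gene) target entries of the subset and reports
#' the fraction carrying `origin`, plus the per-population maximum (the
#' "up to X percent" summary).
#'
#' @param table an [classify_inheritance()] result.
#' @param populations non-empty subset of population ids.
#' @param origin one of `"root_set"`, `"inherited"`, `"de_novo"`.
#' @return list with `pooled` fraction, `per_population` named vector, and
#'   `max` (per-population maximum, NA-removed).
#' @export
aggregate_group_fraction <- function(table, populations,
                                     origin = c("de_novo", "inherited",
                                                "root_set")) {
  stopifnot(inherits(table, "inheritance_table"))
  origin <- match.arg(origin)
  if (!length(populations)) stop("aggregate_group_fraction: empty subset")
  sub <- table[table$population %in% populations, ]
  pooled <- if (nrow(sub)) mean(sub$origin == origin) else 0
  per_pop <- vapply(populations, function(p) {
    s <- sub[sub$population == p, ]
    if (nrow(s)) mean(s$origin == origin) else NA_real_
  }, 1.0)
  list(pooled = pooled, per_population = per_pop,
       max = if (all(is.na(per_pop))) NA_real_ else max(per_pop, na.rm = TRUE))
}
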