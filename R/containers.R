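#' Construct a validated count matrix
#'
#' A `count_matrix` is the pipeline's universal input: a gene x sample matrix
#' of non-negative integer read counts (featureCounts-style), with unique
#' gene identifiers as rownames and unique sample identifiers as colnames.
#' Gene identifiers are opaque strings; no annotation semantics are assumed.
#'
#' Fractional values are rejected rather than rounded: the negative-binomial
#' model downstream assumes counts, and silent rounding hides upstream errors.
#'
#' @param counts numeric matrix of non-negative integers with rownames
#'   (gene ids) and colnames (sample ids).
#' @return an integer matrix of class `count_matrix`.
#' @export
count_matrix <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count_matrix: rownames (gene ids) and colnames (sample ids) are required")
  dup_g <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup_g))
    stop("count_matrix: duplicated gene id(s): ", paste(dup_g, collapse = ", "))
  dup_s <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup_s))
    stop("count_matrix: duplicated sample id(s): ", paste(dup_s, collapse = ", "))
  if (!is.numeric(counts)) stop("count_matrix: counts must be numeric")
  bad <- which(counts < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("count_matrix: negative count %s at gene '%s', sample '%s'",
                 format(counts[bad[1, , drop = FALSE]]),
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  frac <- which(abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)
  if (nrow(frac))
    stop(sprintf("count_matrix: non-integer count %s at gene '%s', sample '%s'",
                 format(counts[frac[1, , drop = FALSE]]),
                 rownames(counts)[frac[1, 1]], colnames(counts)[frac[1, 2]]))
  storage.mode(counts) <- "integer"
  class(counts) <- c("count_matrix", class(counts))
  counts
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n", nrow(x), ncol(x)))
  invisible(x)
}

VALID_ASSAYS <- c("IP", "INPUT")
VALID_CONDITIONS <- c("WT", "KO", "NA")

#' Construct a validated sample sheet
#'
#' Maps each sample to its cell population, assay fraction (IP or INPUT),
#' genotype condition (WT, KO, or NA when not applicable) and replicate
#' number.  Categorical fields are case-normalized on construction so that
#' hand-edited sheets ("ip", "wt") do not cause silent stratum mismatches.
#'
#' @param df data.frame with columns `sample_id`, `population`, `assay`,
#'   `condition`, `replicate`.
#' @return data.frame of class `sample_sheet`.
#' @export
sample_sheet <- function(df) {
  req <- c("sample_id", "population", "assay", "condition", "replicate")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("sample_sheet: missing required column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[req]
  df$sample_id <- as.character(df$sample_id)
  df$population <- as.character(df$population)
  df$assay <- toupper(trimws(as.character(df$assay)))
  df$condition <- toupper(trimws(as.character(df$condition)))
  df$condition[is.na(df$condition) | df$condition == ""] <- "NA"
  df$replicate <- as.integer(df$replicate)
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup))
    stop("sample_sheet: duplicated sample id(s): ", paste(dup, collapse = ", "))
  bad_a <- setdiff(unique(df$assay), VALID_ASSAYS)
  if (length(bad_a))
    stop("sample_sheet: invalid assay value(s): ", paste(bad_a, collapse = ", "),
         " (expected IP or INPUT)")
  bad_c <- setdiff(unique(df$condition), VALID_CONDITIONS)
  if (length(bad_c))
    stop("sample_sheet: invalid condition value(s): ", paste(bad_c, collapse = ", "))
  if (any(is.na(df$replicate)) || any(df$replicate < 1))
    stop("sample_sheet: replicate must be a positive integer")
  class(df) <- c("sample_sheet", class(df))
  df
}

#' Construct a rooted developmental hierarchy from an edge list
#'
#' The hierarchy is a rooted tree over population identifiers: exactly one
#' root (no incoming edge), every non-root node has exactly one parent, and
#' no cycles.
#'
#' @param edges data.frame or 2-column matrix of (parent, child) pairs.
#' @return object of class `hierarchy_tree`: list with `nodes`, `edges`,
#'   `root`, and a named `parent` lookup vector.
#' @export
hierarchy_tree <- function(edges) {
  edges <- as.data.frame(edges)
  if (ncol(edges) < 2) stop("hierarchy_tree: edges need two columns (parent, child)")
  names(edges)[1:2] <- c("parent", "child")
  edges$parent <- as.character(edges$parent)
  edges$child <- as.character(edges$child)
  if (nrow(edges) == 0) stop("hierarchy_tree: empty edge list")
  dup <- unique(edges$child[duplicated(edges$child)])
  if (length(dup))
    stop("hierarchy_tree: node(s) with more than one parent: ",
         paste(dup, collapse = ", "))
  nodes <- unique(c(edges$parent, edges$child))
  roots <- setdiff(nodes, edges$child)
  if (length(roots) == 0)
    stop("hierarchy_tree: no root found (cycle in edge list)")
  if (length(roots) > 1)
    stop("hierarchy_tree: multiple roots: ", paste(roots, collapse = ", "))
  parent <- stats::setNames(edges$parent, edges$child)
  # walk each node to the root; revisiting a node means a cycle
  for (n in nodes) {
    seen <- character(0)
    cur <- n
    while (cur %in% names(parent)) {
      if (cur %in% seen) stop("hierarchy_tree: cycle detected at node ", cur)
      seen <- c(seen, cur)
      cur <- parent[[cur]]
    }
  }
  structure(list(nodes = nodes, edges = edges[, c("parent", "child")],
                 root = roots, parent = parent),
            class = "hierarchy_tree")
}

#' @export
print.hierarchy_tree <- function(x, ...) {
  cat(sprintf("hierarchy_tree: %d nodes, root '%s'\n", length(x$nodes), x$root))
  invisible(x)
}

#' Ancestors of a node, nearest first
#'
#' @param tree a [hierarchy_tree()].
#' @param node node identifier.
#' @return character vector of ancestors ordered parent, grandparent, ...,
#'   root; empty for the root itself.
#' @export
tree_ancestors <- function(tree, node) {
  stopifnot(inherits(tree, "hierarchy_tree"))
  if (!node %in% tree$nodes) stop("tree_ancestors: unknown node ", node)
  anc <- character(0)
  cur <- node
  while (cur %in% names(tree$parent)) {
    cur <- tree$parent[[cur]]
    anc <- c(anc, cur)
  }
  anc
}

#' Nodes in topological (root-first) order
#' @param tree a [hierarchy_tree()].
#' @return character vector of node ids, every parent before its children.
#' @export
tree_topological_order <- function(tree) {
  stopifnot(inherits(tree, "hierarchy_tree"))
  ord <- tree$root
  repeat {
    nxt <- tree$edges$child[tree$edges$parent %in% ord &
                              !tree$edges$child %in% ord]
    if (!length(nxt)) break
    ord <- c(ord, nxt)
  }
  ord
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors of gene ids.
#' @return named list of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("gene_set_collection: all sets must be named")
  dup <- unique(names(sets)[duplicated(names(sets))])
  if (length(dup))
    stop("gene_set_collection: duplicated set name(s): ", paste(dup, collapse = ", "))
  if (any(vapply(sets, length, 1L) == 0))
    stop("gene_set_collection: empty set(s) not allowed")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  class(sets) <- c("gene_set_collection", class(sets))
  sets
}
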