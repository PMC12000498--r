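#' Build the m6A + expression feature matrix for co-clustering
#'
#' Rows are complete-case genes: scored (non-missing Z) in every
#' population and present in the expression matrix — K-means has no
#' principled missing-data treatment, and called targets are scored by
#' construction.  Each row concatenates the mean-centered m6A Z profile
#' with the mean-centered log2 expression profile; each channel is then
#' standardized to pooled variance 1 so neither dominates the distance.
#'
#' @param landscape an [assemble_landscape()] result.
#' @param expression gene x population matrix of normalized expression
#'   means (linear scale; log-transformed internally as log2(x + 1)).
#' @param genes optional gene subset (default: all landscape genes).
#' @param log_expression apply log2(x + 1) to the expression channel.
#' @return gene x (2 * n_populations) numeric matrix; columns named
#'   `m6a.<pop>` and `expr.<pop>`.
#' @export
build_feature_matrix <- function(landscape, expression, genes = NULL,
                                 log_expression = TRUE) {
  stopifnot(inherits(landscape, "m6a_landscape"))
  pops <- landscape$populations
  if (!all(pops %in% colnames(expression)))
    stop("build_feature_matrix: expression is missing population(s): ",
         paste(setdiff(pops, colnames(expression)), collapse = ", "))
  if (is.null(genes)) genes <- landscape$genes
  genes <- intersect(genes, intersect(landscape$genes, rownames(expression)))
  complete <- genes[rowSums(is.na(landscape$z[genes, pops, drop = FALSE])) == 0]
  if (!length(complete))
    stop("build_feature_matrix: no complete-case genes in the intersection")
  zc <- mean_center_profiles(landscape$z[complete, pops, drop = FALSE])
  ex <- expression[complete, pops, drop = FALSE]
  if (log_expression) ex <- log2(ex + 1)
  exc <- mean_center_profiles(ex)
  pool_sd <- function(m) {
    s <- sqrt(mean(m^2))       # channel already centered per row
    if (s > 0) m / s else m
  }
  out <- cbind(pool_sd(zc), pool_sd(exc))
  colnames(out) <- c(paste0("m6a.", pops), paste0("expr.", pops))
  out
}

# squared Euclidean distances rows of X to rows of C
.dist2 <- function(X, C) {
  outer(rowSums(X^2), rowSums(C^2), "+") - 2 * X %*% t(C)
}

# k-means++ seeding (Arthur & Vassilvitskii): first center uniform, then
# proportional to squared distance from the nearest chosen center
.kmeanspp_init <- function(X, K) {
  n <- nrow(X)
  centers <- integer(K)
  centers[1] <- sample.int(n, 1)
  d2 <- pmax(.dist2(X, X[centers[1], , drop = FALSE])[, 1], 0)
  if (K > 1) for (k in 2:K) {
    if (sum(d2) == 0) {
      centers[k] <- sample.int(n, 1)
    } else {
      centers[k] <- sample.int(n, 1, prob = d2)
    }
    d2 <- pmin(d2, pmax(.dist2(X, X[centers[k], , drop = FALSE])[, 1], 0))
  }
  X[centers, , drop = FALSE]
}

.lloyd <- function(X, C, max_iter = 100) {
  K <- nrow(C)
  assign_prev <- rep(0L, nrow(X))
  for (it in seq_len(max_iter)) {
    d2 <- .dist2(X, C)
    assign <- max.col(-d2, ties.method = "first")
    # re-seed empty clusters with the point farthest from its center
    for (k in which(tabulate(assign, K) == 0)) {
      far <- which.max(d2[cbind(seq_len(nrow(X)), assign)])
      C[k, ] <- X[far, ]
      assign[far] <- k
      d2 <- .dist2(X, C)
      assign <- max.col(-d2, ties.method = "first")
    }
    if (identical(assign, assign_prev)) break
    assign_prev <- assign
    for (k in seq_len(K))
      C[k, ] <- colMeans(X[assign == k, , drop = FALSE])
  }
  d2 <- .dist2(X, C)
  inertia <- sum(pmax(d2[cbind(seq_len(nrow(X)), assign)], 0))
  list(assign = assign, centers = C, inertia = inertia)
}

#' K-means clustering with k-means++ restarts
#'
#' Lloyd's algorithm with k-means++ initialization, `n_init` restarts
#' keeping the best (lowest inertia) solution; fully deterministic given
#' `seed`.  Cluster labels are renumbered by descending cluster size, ties
#' broken by the smallest member gene id, so labels are stable across runs.
#'
#' @param x numeric matrix (genes x features), rownames = gene ids.
#' @param K number of clusters (1 <= K <= nrow(x)).
#' @param seed RNG seed.
#' @param n_init number of restarts.
#' @param max_iter Lloyd iterations per restart.
#' @return object of class `cluster_assignment`: list with `cluster`
#'   (named integer vector), `K`, `seed`, `n_init`, `inertia`, `centers`.
#' @export
kmeans_cluster <- function(x, K, seed = 1, n_init = 10, max_iter = 100) {
  x <- as.matrix(x)
  if (K < 1) stop("kmeans_cluster: K must be >= 1")
  if (K > nrow(x)) stop("kmeans_cluster: K exceeds the number of rows")
  set.seed(seed)
  best <- NULL
  for (i in seq_len(n_init)) {
    C <- .kmeanspp_init(x, K)
    fit <- .lloyd(x, C, max_iter)
    if (is.null(best) || fit$inertia < best$inertia - 1e-12) best <- fit
  }
  # deterministic relabelling: descending size, ties by smallest gene id
  sizes <- tabulate(best$assign, K)
  first_gene <- vapply(seq_len(K), function(k) {
    ids <- rownames(x)[best$assign == k]
    if (length(ids)) min(ids) else ""
  }, "")
  new_order <- order(-sizes, first_gene)
  relabel <- integer(K)
  relabel[new_order] <- seq_len(K)
  cl <- relabel[best$assign]
  structure(list(cluster = stats::setNames(cl, rownames(x)), K = K,
                 seed = seed, n_init = n_init, inertia = best$inertia,
                 centers = best$centers[new_order, , drop = FALSE]),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: K = %d, n = %d, inertia = %.4g\n",
              x$K, length(x$cluster), x$inertia))
  print(table(x$cluster))
  invisible(x)
}

#' Per-cluster correlation between mean m6A and mean expression profiles
#'
#' For each cluster, the member genes' m6A Z profiles and log2 expression
#' profiles are averaged across genes, and the Pearson correlation of the
#' two cluster-mean profiles across populations is reported with its sign
#' and two-sided t p-value.  Pearson on population-level means is the
#' default (n is small; rank correlation would be coarse); `method` is
#' configurable.
#'
#' @param assignment a [kmeans_cluster()] result.
#' @param z gene x population m6A Z matrix (complete rows for clustered
#'   genes).
#' @param expression gene x population expression matrix (linear; logged
#'   internally as in [build_feature_matrix()]).
#' @param method correlation method (default `"pearson"`).
#' @param log_expression apply log2(x + 1) to expression.
#' @return data.frame cluster, n_genes, r, sign, p_value, flag.
#' @export
cluster_correlation_sign <- function(assignment, z, expression,
                                     method = "pearson",
                                     log_expression = TRUE) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  pops <- intersect(colnames(z), colnames(expression))
  if (length(pops) < 3)
    stop("cluster_correlation_sign: need >= 3 shared populations")
  if (log_expression) expression <- log2(expression + 1)
  out <- lapply(sort(unique(assignment$cluster)), function(k) {
    genes <- names(assignment$cluster)[assignment$cluster == k]
    mz <- colMeans(z[genes, pops, drop = FALSE])
    me <- colMeans(expression[genes, pops, drop = FALSE])
    if (stats::sd(mz) == 0 || stats::sd(me) == 0)
      return(data.frame(cluster = k, n_genes = length(genes), r = NA_real_,
                        sign = NA_integer_, p_value = NA_real_,
                        flag = "zero_variance"))
    ct <- stats::cor.test(mz, me, method = method)
    data.frame(cluster = k, n_genes = length(genes),
               r = unname(ct$estimate), sign = sign(unname(ct$estimate)),
               p_value = ct$p.value, flag = "")
  })
  do.call(rbind, out)
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test per set: with universe size N, K
#' annotated genes, n selected genes and overlap k, p = P(X >= k).  Sets
#' are intersected with the universe first; BH adjustment is over sets.
#'
#' @param selected character vector of selected genes (subset of
#'   `universe`).
#' @param collection a [gene_set_collection()].
#' @param universe character vector, the gene universe.
#' @return data.frame set, universe_n, annotated_k, selected_n, overlap_k,
#'   p_value, p_adj.
#' @export
hypergeometric_enrichment <- function(selected, collection, universe) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("hypergeometric_enrichment: empty universe")
  selected <- unique(as.character(selected))
  if (!all(selected %in% universe))
    stop("hypergeometric_enrichment: selected genes must be in the universe")
  N <- length(universe)
  n <- length(selected)
  out <- lapply(names(collection), function(nm) {
    ann <- intersect(collection[[nm]], universe)
    K <- length(ann)
    k <- length(intersect(ann, selected))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, universe_n = N, annotated_k = K, selected_n = n,
               overlap_k = k, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$p_adj <- benjamini_hochberg(out$p_value)
  out
}

#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie ARI; 1 for identical partitions (up to relabelling), ~0
#' for independent ones.  Used to score cluster recovery against planted
#' truth.
#'
#' @param a,b vectors of cluster labels of equal length.
#' @return numeric ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("adjusted_rand_index: length mismatch")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
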