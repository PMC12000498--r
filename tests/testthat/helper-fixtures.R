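# shared fixture builders; everything is generated in code, no files

make_counts <- function(m, genes = NULL, samples = NULL) {
  if (is.null(genes)) genes <- sprintf("G%d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("S%d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  count_matrix(m)
}

# minimal enrichment_result for threshold / landscape logic tests
make_result <- function(genes, log2fc, p, wald = NULL) {
  if (is.null(wald)) wald <- log2fc / 0.3
  out <- data.frame(gene = genes, base_mean = 50, log2fc = log2fc, se = 0.3,
                    wald_stat = wald, p_value = p, n_eff = 4L, flag = "",
                    stringsAsFactors = FALSE)
  class(out) <- c("enrichment_result", class(out))
  out
}

# fabricate an m6a_landscape directly from z / target matrices
make_landscape <- function(z, tgt, lfc_thresh = 1, p_thresh = 0.05) {
  structure(list(populations = colnames(z), genes = rownames(z), z = z,
                 is_target = tgt,
                 thresholds = list(lfc_thresh = lfc_thresh,
                                   p_thresh = p_thresh)),
            class = "m6a_landscape")
}

chain_tree <- function(nodes) {
  hierarchy_tree(data.frame(parent = nodes[-length(nodes)],
                            child = nodes[-1]))
}

# ---- small-tree enumeration (Prüfer) and an independent inheritance oracle

# decode a Prüfer sequence over labels 1..n into undirected edges
prufer_decode <- function(seq, n) {
  degree <- rep(1L, n)
  for (s in seq) degree[s] <- degree[s] + 1L
  edges <- matrix(0L, 0, 2)
  for (s in seq) {
    leaf <- min(which(degree == 1L))
    edges <- rbind(edges, c(leaf, s))
    degree[leaf] <- degree[leaf] - 1L
    degree[s] <- degree[s] - 1L
  }
  u <- which(degree == 1L)
  rbind(edges, u)
}

# all rooted labelled trees on n >= 2 nodes as (parent, child) data.frames
all_rooted_trees <- function(n) {
  seqs <- if (n == 2) list(integer(0)) else {
    grid <- do.call(expand.grid, rep(list(seq_len(n)), n - 2))
    lapply(seq_len(nrow(grid)), function(i) as.integer(grid[i, ]))
  }
  out <- list()
  for (s in seqs) {
    und <- prufer_decode(s, n)
    adj <- lapply(seq_len(n), function(v)
      c(und[und[, 1] == v, 2], und[und[, 2] == v, 1]))
    for (root in seq_len(n)) {
      # orient away from root by BFS
      parent <- rep(NA_integer_, n)
      queue <- root
      visited <- rep(FALSE, n)
      visited[root] <- TRUE
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        for (w in adj[[v]]) if (!visited[w]) {
          visited[w] <- TRUE
          parent[w] <- v
          queue <- c(queue, w)
        }
      }
      kids <- which(!is.na(parent))
      out[[length(out) + 1]] <- data.frame(
        parent = paste0("N", parent[kids]), child = paste0("N", kids),
        stringsAsFactors = FALSE)
    }
  }
  out
}

# independent classification oracle: explicit root-path enumeration over the
# raw edge list, no use of hierarchy_tree internals
oracle_inheritance <- function(tgt, edges, mode) {
  parent_of <- function(node) {
    hit <- edges$parent[edges$child == node]
    if (length(hit)) hit else NA_character_
  }
  root <- setdiff(unique(c(edges$parent, edges$child)), edges$child)
  out <- list()
  for (pop in colnames(tgt)) for (g in rownames(tgt)) {
    if (!isTRUE(tgt[g, pop])) next
    if (pop == root) {
      out[[length(out) + 1]] <- data.frame(population = pop, gene = g,
                                           origin = "root_set", evidence = "")
      next
    }
    # full path to root
    path <- character(0)
    cur <- pop
    repeat {
      cur <- parent_of(cur)
      if (is.na(cur)) break
      path <- c(path, cur)
    }
    if (mode == "parent") path <- path[1]
    carriers <- path[vapply(path, function(a)
      a %in% colnames(tgt) && isTRUE(tgt[g, a]), TRUE)]
    if (length(carriers)) {
      out[[length(out) + 1]] <- data.frame(population = pop, gene = g,
                                           origin = "inherited",
                                           evidence = carriers[1])
    } else {
      out[[length(out) + 1]] <- data.frame(population = pop, gene = g,
                                           origin = "de_novo", evidence = "")
    }
  }
  if (!length(out))
    return(data.frame(population = character(0), gene = character(0),
                      origin = character(0), evidence = character(0)))
  do.call(rbind, out)
}
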