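#' Simulation parameters for the landscape generator
#'
#' Defaults state the emulated design: 8 populations on a rooted skeletal
#' hierarchy, paired IP/INPUT libraries with 2 biological replicates,
#' negative-binomial counts, a methylated subset propagating down the tree.
#'
#' @param n_genes number of genes.
#' @param tree a [hierarchy_tree()] of populations.
#' @param frac_methylated_root fraction of genes methylated at the root.
#' @param p_inherit probability a child is methylated given a methylated
#'   parent (first-order Markov propagation).
#' @param p_denovo probability a child is methylated given an unmethylated
#'   parent.
#' @param enrichment_lfc true log2 IP/INPUT enrichment of methylated genes.
#' @param dispersion NB dispersion alpha (variance = mu + alpha mu^2); 0
#'   gives Poisson counts.
#' @param mean_depth mean per-gene baseline count at size factor 1.
#' @param n_reps biological replicates per (population, assay) stratum.
#' @param seed integer RNG seed.
#' @return validated list of class `simulation_params`.
#' @export
simulation_params <- function(n_genes = 5000, tree = default_tree(),
                              frac_methylated_root = 0.3, p_inherit = 0.8,
                              p_denovo = 0.1, enrichment_lfc = 2,
                              dispersion = 0.1, mean_depth = 50,
                              n_reps = 2, seed = 1) {
  stopifnot(inherits(tree, "hierarchy_tree"))
  if (n_genes < 1) stop("simulation_params: n_genes must be >= 1")
  for (p in c(frac_methylated_root = frac_methylated_root,
              p_inherit = p_inherit, p_denovo = p_denovo)) {
    if (p < 0 || p > 1) stop("simulation_params: probabilities must be in [0, 1]")
  }
  if (enrichment_lfc <= 0) stop("simulation_params: enrichment_lfc must be > 0")
  if (dispersion < 0) stop("simulation_params: dispersion must be >= 0")
  if (mean_depth <= 0) stop("simulation_params: mean_depth must be > 0")
  if (n_reps < 1) stop("simulation_params: n_reps must be >= 1")
  structure(list(n_genes = as.integer(n_genes), tree = tree,
                 frac_methylated_root = frac_methylated_root,
                 p_inherit = p_inherit, p_denovo = p_denovo,
                 enrichment_lfc = enrichment_lfc, dispersion = dispersion,
                 mean_depth = mean_depth, n_reps = as.integer(n_reps),
                 seed = as.integer(seed)),
            class = "simulation_params")
}

#' Default skeletal hierarchy fixture
#'
#' The stem-to-progenitor chain SSC -> pBCSP -> BCSP with the five
#' downstream populations (PCP, Thy, BLSP, 6C3, HEC) attached to BCSP.
#' The exact branching below BCSP is a documented modelling choice; the
#' tree is always a user-suppliable input.
#'
#' @return a [hierarchy_tree()].
#' @export
default_tree <- function() {
  hierarchy_tree(data.frame(
    parent = c("SSC", "pBCSP", rep("BCSP", 5)),
    child = c("pBCSP", "BCSP", "PCP", "Thy", "BLSP", "6C3", "HEC")))
}

rnb <- function(n, mu, alpha) {
  if (alpha == 0) stats::rpois(n, mu) else stats::rnbinom(n, size = 1 / alpha, mu = mu)
}

#' Simulate IP/INPUT counts across a developmental hierarchy
#'
#' Gene baseline means are log-normal (sdlog 1, meanlog tied to
#' `mean_depth`); library-size factors are uniform on \[0.5, 2\] so that
#' normalization is exercised; INPUT counts are NB(mu_g s_j, alpha) and IP
#' counts NB(mu_g s_j 2^lfc, alpha) where lfc is the planted enrichment of
#' methylated genes and 0 otherwise.  Methylation propagates root-to-leaf by
#' immediate parent state: a child is methylated with probability
#' `p_inherit` when the parent is methylated and `p_denovo` otherwise, and
#' the realized origin labels (root_set / inherited / de_novo / absent) are
#' returned as ground truth.
#'
#' @param params a [simulation_params()].
#' @return list with `counts` ([count_matrix()]), `samples`
#'   ([sample_sheet()]), `truth` (data.frame gene, population, methylated,
#'   origin, true_lfc) and `size_factors` (the generative truth).
#' @export
simulate_landscape_counts <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(params$seed)
  tree <- params$tree
  pops <- tree_topological_order(tree)
  genes <- sprintf("G%05d", seq_len(params$n_genes))

  # heavy-tailed expression: lognormal with mean = mean_depth
  mu_g <- stats::rlnorm(params$n_genes,
                        meanlog = log(params$mean_depth) - 0.5, sdlog = 1)

  meth <- matrix(FALSE, params$n_genes, length(pops),
                 dimnames = list(genes, pops))
  origin <- matrix("absent", params$n_genes, length(pops),
                   dimnames = list(genes, pops))
  meth[, tree$root] <- stats::runif(params$n_genes) < params$frac_methylated_root
  origin[meth[, tree$root], tree$root] <- "root_set"
  for (pop in pops[-1]) {
    par <- tree$parent[[pop]]
    p <- ifelse(meth[, par], params$p_inherit, params$p_denovo)
    meth[, pop] <- stats::runif(params$n_genes) < p
    origin[meth[, pop] & meth[, par], pop] <- "inherited"
    origin[meth[, pop] & !meth[, par], pop] <- "de_novo"
  }

  n_samp <- length(pops) * 2L * params$n_reps
  sf <- stats::runif(n_samp, 0.5, 2)
  counts <- matrix(0L, params$n_genes, n_samp)
  ids <- character(n_samp)
  meta <- vector("list", n_samp)
  j <- 0L
  for (pop in pops) {
    lfc <- ifelse(meth[, pop], params$enrichment_lfc, 0)
    for (assay in c("IP", "INPUT")) {
      fold <- if (assay == "IP") 2^lfc else rep(1, params$n_genes)
      for (r in seq_len(params$n_reps)) {
        j <- j + 1L
        ids[j] <- sprintf("%s_%s_%d", pop, assay, r)
        counts[, j] <- rnb(params$n_genes, mu_g * sf[j] * fold,
                           params$dispersion)
        meta[[j]] <- data.frame(sample_id = ids[j], population = pop,
                                assay = assay, condition = "NA",
                                replicate = r)
      }
    }
  }
  dimnames(counts) <- list(genes, ids)
  truth <- data.frame(gene = rep(genes, length(pops)),
                      population = rep(pops, each = params$n_genes),
                      methylated = as.vector(meth),
                      origin = as.vector(origin),
                      true_lfc = ifelse(as.vector(meth),
                                        params$enrichment_lfc, 0),
                      stringsAsFactors = FALSE)
  list(counts = count_matrix(counts),
       samples = sample_sheet(do.call(rbind, meta)),
       truth = truth,
       size_factors = stats::setNames(sf, ids))
}

#' Simulate a two-condition (WT vs KO) expression contrast
#'
#' A `frac_de` subset of genes is shifted in the KO group by `+lfc_de` or
#' `-lfc_de` (sign random, balanced in expectation); truth flags give the
#' planted direction.
#'
#' @param n_genes,n_reps genes and replicates per condition.
#' @param frac_de fraction of genes differentially expressed.
#' @param lfc_de absolute planted log2 fold change (KO vs WT).
#' @param dispersion,mean_depth NB dispersion and baseline depth, as in
#'   [simulate_landscape_counts()].
#' @param seed RNG seed.
#' @return list with `counts`, `samples`, and `truth` (data.frame gene,
#'   direction in up/down/null, true_lfc).
#' @export
simulate_de_counts <- function(n_genes = 4000, n_reps = 2, frac_de = 0.05,
                               lfc_de = 1, dispersion = 0.1, mean_depth = 50,
                               seed = 1) {
  if (frac_de < 0 || frac_de > 1) stop("simulate_de_counts: frac_de must be in [0, 1]")
  if (dispersion < 0) stop("simulate_de_counts: dispersion must be >= 0")
  if (mean_depth <= 0) stop("simulate_de_counts: mean_depth must be > 0")
  set.seed(seed)
  genes <- sprintf("G%05d", seq_len(n_genes))
  mu_g <- stats::rlnorm(n_genes, meanlog = log(mean_depth) - 0.5, sdlog = 1)
  is_de <- stats::runif(n_genes) < frac_de
  sign_de <- ifelse(stats::runif(n_genes) < 0.5, 1, -1)
  lfc <- ifelse(is_de, sign_de * lfc_de, 0)

  n_samp <- 2L * n_reps
  sf <- stats::runif(n_samp, 0.5, 2)
  cond <- rep(c("WT", "KO"), each = n_reps)
  ids <- sprintf("%s_%d", cond, rep(seq_len(n_reps), 2))
  counts <- matrix(0L, n_genes, n_samp, dimnames = list(genes, ids))
  for (j in seq_len(n_samp)) {
    fold <- if (cond[j] == "KO") 2^lfc else rep(1, n_genes)
    counts[, j] <- rnb(n_genes, mu_g * sf[j] * fold, dispersion)
  }
  samples <- sample_sheet(data.frame(
    sample_id = ids, population = "SSC", assay = "INPUT",
    condition = cond, replicate = rep(seq_len(n_reps), 2)))
  truth <- data.frame(gene = genes,
                      direction = ifelse(!is_de, "null",
                                         ifelse(sign_de > 0, "up", "down")),
                      true_lfc = lfc, stringsAsFactors = FALSE)
  list(counts = count_matrix(counts), samples = samples, truth = truth)
}

#' Simulate mRNA decay time courses
#'
#' Relative abundance follows first-order decay, C/C0(t) = 2^(-t / t_half),
#' perturbed at t > 0 by multiplicative log-normal noise of standard
#' deviation `noise_sd` (on the natural-log scale); C/C0(0) is fixed at 1
#' because C0 is the normalizer.
#'
#' @param true_half_life_h true half-life in hours (> 0).
#' @param times_h time points in hours; must include 0.
#' @param noise_sd log-scale noise SD (>= 0).
#' @param n_curves number of replicate curves.
#' @param seed RNG seed.
#' @return list with `curves` (list of data.frames time_h, rel_abundance)
#'   and `truth` (true_half_life_h, k_decay).
#' @export
simulate_decay <- function(true_half_life_h = 3, times_h = c(0, 2, 4, 8),
                           noise_sd = 0.05, n_curves = 1, seed = 1) {
  if (true_half_life_h <= 0) stop("simulate_decay: half-life must be > 0")
  if (noise_sd < 0) stop("simulate_decay: noise_sd must be >= 0")
  if (!0 %in% times_h) stop("simulate_decay: times must include 0")
  if (is.unsorted(times_h, strictly = TRUE))
    stop("simulate_decay: times must be strictly increasing")
  set.seed(seed)
  curves <- lapply(seq_len(n_curves), function(i) {
    rel <- 2^(-times_h / true_half_life_h)
    noise <- exp(stats::rnorm(length(times_h), 0, noise_sd))
    noise[times_h == 0] <- 1
    data.frame(time_h = times_h, rel_abundance = rel * noise)
  })
  list(curves = curves,
       truth = list(true_half_life_h = true_half_life_h,
                    k_decay = log(2) / true_half_life_h))
}
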