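# stage-level RNG streams derived from the one global seed, kept < 2^31
stage_seed <- function(seed, idx) {
  as.integer((as.numeric(seed) %% 2147483647) * 31 + idx * 10007) %% 2147483647L
}

#' IP-vs-INPUT enrichment for one population
#'
#' Subsets the count matrix to one population's IP and INPUT samples,
#' normalizes within the contrast, estimates dispersion and runs the NB
#' Wald test with IP as numerator.
#'
#' @param counts a [count_matrix()].
#' @param samples a [sample_sheet()].
#' @param population population id.
#' @param min_total_count low-count filter (see [nb_wald_test()]).
#' @return an `enrichment_result` data.frame.
#' @export
quantify_population <- function(counts, samples, population,
                                min_total_count = 10) {
  sel <- samples$population == population & samples$assay %in% c("IP", "INPUT")
  if (!any(sel)) stop("quantify_population: no samples for population ", population)
  sub <- samples[sel, ]
  if (!all(c("IP", "INPUT") %in% sub$assay))
    stop("quantify_population: population ", population,
         " lacks an IP or INPUT stratum")
  cm <- unclass(counts)[, sub$sample_id, drop = FALSE]
  groups <- factor(sub$assay, levels = c("INPUT", "IP"))  # IP = numerator
  sf <- size_factors(cm)
  disp <- estimate_dispersion(cm, groups, sf)
  nb_wald_test(cm, groups, sf, disp, min_total_count)
}

#' IP-vs-INPUT enrichment for every population in a sample sheet
#' @inheritParams quantify_population
#' @param populations subset of populations (default: all with IP samples).
#' @return named list of `enrichment_result`, one per population.
#' @export
quantify_all <- function(counts, samples, populations = NULL,
                         min_total_count = 10) {
  if (is.null(populations))
    populations <- unique(samples$population[samples$assay == "IP"])
  res <- lapply(populations, function(p)
    quantify_population(counts, samples, p, min_total_count))
  names(res) <- populations
  res
}

#' Per-population normalized mean expression from INPUT libraries
#'
#' The expression channel of the integration step: for each population,
#' the mean of size-factor-normalized counts over that population's INPUT
#' samples (input libraries are ordinary RNA-seq of the same cells).
#' Normalization is across all INPUT samples jointly so population means
#' are comparable.
#'
#' @param counts a [count_matrix()].
#' @param samples a [sample_sheet()].
#' @return gene x population numeric matrix (linear scale).
#' @export
population_expression <- function(counts, samples) {
  sel <- samples$assay == "INPUT"
  if (!any(sel)) stop("population_expression: no INPUT samples")
  sub <- samples[sel, ]
  cm <- unclass(counts)[, sub$sample_id, drop = FALSE]
  sf <- size_factors(cm)
  y <- sweep(cm, 2, sf, "/")
  pops <- unique(sub$population)
  out <- vapply(pops, function(p)
    rowMeans(y[, sub$sample_id[sub$population == p], drop = FALSE]),
    numeric(nrow(y)))
  colnames(out) <- pops
  out
}

default_config <- function() {
  list(
    seed = 1,
    stages = c("simulate", "quantify", "landscape", "inherit", "cluster",
               "de", "decay"),
    simulate = list(n_genes = 2000, frac_methylated_root = 0.3,
                    p_inherit = 0.8, p_denovo = 0.1, enrichment_lfc = 2,
                    dispersion = 0.1, mean_depth = 50, n_reps = 2),
    quantify = list(min_total_count = 10),
    landscape = list(lfc_thresh = 1, p_thresh = 0.05),
    inherit = list(mode = "any_ancestor"),
    cluster = list(K = 2, n_init = 10, genes = "targets", gmt = NULL),
    de = list(n_genes = 2000, n_reps = 2, frac_de = 0.05, lfc_de = 1,
              dispersion = 0.1, mean_depth = 50, lfc_thresh = 0.5,
              p_thresh = 0.05),
    decay = list(true_half_life_h = 3, times_h = c(0, 2, 4, 8),
                 noise_sd = 0.05, n_curves = 20),
    inputs = list()
  )
}

merge_config <- function(base, user) {
  for (k in names(user)) {
    if (is.list(base[[k]]) && is.list(user[[k]]) &&
        !is.null(names(user[[k]]))) {
      base[[k]] <- merge_config(base[[k]], user[[k]])
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

validate_config <- function(cfg) {
  for (nm in c("landscape", "de")) {
    p <- cfg[[nm]]$p_thresh
    if (!is.numeric(p) || p <= 0 || p > 1)
      stop("config error: ", nm, "$p_thresh must be in (0, 1]")
    l <- cfg[[nm]]$lfc_thresh
    if (!is.numeric(l) || l <= 0)
      stop("config error: ", nm, "$lfc_thresh must be > 0")
  }
  if (!is.numeric(cfg$cluster$K) || cfg$cluster$K < 1)
    stop("config error: cluster$K must be >= 1")
  if (!is.numeric(cfg$quantify$min_total_count) ||
      cfg$quantify$min_total_count < 0)
    stop("config error: quantify$min_total_count must be >= 0")
  bad <- setdiff(cfg$stages, default_config()$stages)
  if (length(bad)) stop("config error: unknown stage(s): ",
                        paste(bad, collapse = ", "))
  invisible(cfg)
}

flatten_params <- function(x, prefix = "") {
  out <- character(0)
  for (k in names(x)) {
    v <- x[[k]]
    key <- if (nzchar(prefix)) paste0(prefix, ".", k) else k
    if (is.list(v) && !is.null(names(v)) && length(v)) {
      out <- c(out, flatten_params(v, key))
    } else if (is.null(v) || (is.list(v) && !length(v))) {
      out <- c(out, sprintf("%s=", key))
    } else {
      out <- c(out, sprintf("%s=%s", key,
                            paste(format(unlist(v), digits = 15),
                                  collapse = ",")))
    }
  }
  out
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages — simulate, quantify, landscape, inherit,
#' cluster, de, decay — writing each stage's tables to `out_dir` as
#' commented TSV (see [write_result_tsv()]) plus a log with package
#' version, seed, and a full parameter echo.  Fixed config + fixed seed
#' gives byte-identical outputs across runs.  When `simulate` is not among
#' the stages, `config$inputs` must name `counts` (TSV), `samples` (CSV)
#' and `tree` (edge-list TSV) files.
#'
#' @param config named list, or path to a JSON config file; unset entries
#'   fall back to documented defaults.
#' @param out_dir output directory (created if needed).
#' @param seed optional override of `config$seed`.
#' @return invisibly, a named list of the in-memory stage results.
#' @export
run_pipeline <- function(config = list(), out_dir, seed = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("run_pipeline: config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- merge_config(default_config(), config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  validate_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  state <- list()
  log_lines <- c(sprintf("m6atlas version=%s",
                         as.character(utils::packageVersion("m6atlas"))),
                 sprintf("seed=%d", cfg$seed),
                 sprintf("stages=%s", paste(cfg$stages, collapse = ",")))

  tree <- if (!is.null(cfg$inputs$tree))
    read_tree(cfg$inputs$tree) else default_tree()

  if ("simulate" %in% cfg$stages) {
    sp <- do.call(simulation_params,
                  c(cfg$simulate, list(tree = tree,
                                       seed = stage_seed(cfg$seed, 1))))
    sim <- simulate_landscape_counts(sp)
    state$sim <- sim
    write_counts(sim$counts, file.path(out_dir, "counts.tsv"))
    write_sample_sheet(sim$samples, file.path(out_dir, "samples.csv"))
    write_result_tsv(sim$truth, file.path(out_dir, "truth.tsv"),
                     cfg$simulate)
    write_tree(tree, file.path(out_dir, "tree.tsv"))
  } else if (any(c("quantify", "landscape", "inherit", "cluster") %in%
                 cfg$stages)) {
    for (req in c("counts", "samples")) {
      if (is.null(cfg$inputs[[req]]))
        stop("run_pipeline: missing input '", req,
             "' (no simulate stage requested)")
    }
    state$sim <- list(counts = read_counts(cfg$inputs$counts),
                      samples = read_sample_sheet(cfg$inputs$samples))
  }

  if ("quantify" %in% cfg$stages) {
    res <- quantify_all(state$sim$counts, state$sim$samples,
                        min_total_count = cfg$quantify$min_total_count)
    state$results <- res
    for (pop in names(res))
      write_result_tsv(res[[pop]], file.path(out_dir,
                                             sprintf("enrichment_%s.tsv", pop)),
                       c(list(population = pop), cfg$quantify))
  }

  if ("landscape" %in% cfg$stages) {
    land <- assemble_landscape(state$results, cfg$landscape$lfc_thresh,
                               cfg$landscape$p_thresh)
    state$landscape <- land
    write_result_tsv(landscape_table(land),
                     file.path(out_dir, "landscape.tsv"), cfg$landscape)
    zw <- data.frame(gene = rownames(land$z), land$z, check.names = FALSE)
    write_result_tsv(zw, file.path(out_dir, "landscape_z_wide.tsv"),
                     cfg$landscape)
    log_lines <- c(log_lines,
                   sprintf("union_target_count=%d", union_target_count(land)))
  }

  if ("inherit" %in% cfg$stages) {
    inh <- classify_inheritance(state$landscape, tree, cfg$inherit$mode)
    state$inheritance <- inh
    write_result_tsv(as.data.frame(inh), file.path(out_dir, "inheritance.tsv"),
                     cfg$inherit)
    write_result_tsv(stage_fractions(inh),
                     file.path(out_dir, "stage_fractions.tsv"), cfg$inherit)
  }

  if ("cluster" %in% cfg$stages) {
    expr <- population_expression(state$sim$counts, state$sim$samples)
    genes <- if (identical(cfg$cluster$genes, "targets"))
      union_targets(state$landscape) else NULL
    X <- build_feature_matrix(state$landscape, expr, genes)
    cl <- kmeans_cluster(X, cfg$cluster$K, seed = stage_seed(cfg$seed, 5),
                         n_init = cfg$cluster$n_init)
    state$clusters <- cl
    write_result_tsv(data.frame(gene = names(cl$cluster),
                                cluster = unname(cl$cluster)),
                     file.path(out_dir, "clusters.tsv"),
                     list(K = cl$K, n_init = cl$n_init, inertia = cl$inertia))
    corr <- cluster_correlation_sign(cl, state$landscape$z[rownames(X), ,
                                                           drop = FALSE],
                                     expr[rownames(X), , drop = FALSE])
    state$cluster_correlations <- corr
    write_result_tsv(corr, file.path(out_dir, "cluster_correlations.tsv"),
                     list(K = cl$K))
    if (!is.null(cfg$cluster$gmt) && nzchar(cfg$cluster$gmt)) {
      coll <- read_gmt(cfg$cluster$gmt)
      enr <- hypergeometric_enrichment(rownames(X), coll,
                                       state$landscape$genes)
      state$enrichment <- enr
      write_result_tsv(enr, file.path(out_dir, "geneset_enrichment.tsv"),
                       list(gmt = cfg$cluster$gmt))
    }
  }

  if ("de" %in% cfg$stages) {
    de_sim <- do.call(simulate_de_counts,
                      c(cfg$de[c("n_genes", "n_reps", "frac_de", "lfc_de",
                                 "dispersion", "mean_depth")],
                        list(seed = stage_seed(cfg$seed, 6))))
    sub <- de_sim$samples
    groups <- factor(sub$condition, levels = c("WT", "KO"))  # KO = numerator
    sf <- size_factors(de_sim$counts)
    res <- nb_wald_test(de_sim$counts, groups, sf,
                        min_total_count = cfg$quantify$min_total_count)
    degs <- call_degs(res, cfg$de$lfc_thresh, cfg$de$p_thresh)
    state$de <- list(sim = de_sim, results = res, degs = degs)
    if (!is.null(state$landscape)) {
      pop <- if (!is.null(cfg$de$population)) cfg$de$population else tree$root
      shared <- intersect(degs$gene, state$landscape$genes)
      ov <- overlay_m6a(degs[degs$gene %in% shared, ], state$landscape, pop)
      state$de$overlay <- ov
      write_result_tsv(ov$table, file.path(out_dir, "degs.tsv"), cfg$de)
      write_result_tsv(data.frame(n_up_tagged = ov$n_up_tagged,
                                  n_down_tagged = ov$n_down_tagged,
                                  n_tagged = ov$n_tagged),
                       file.path(out_dir, "deg_summary.tsv"), cfg$de)
    } else {
      write_result_tsv(as.data.frame(degs), file.path(out_dir, "degs.tsv"),
                       cfg$de)
    }
  }

  if ("decay" %in% cfg$stages) {
    dk <- do.call(simulate_decay,
                  c(cfg$decay, list(seed = stage_seed(cfg$seed, 7))))
    long <- do.call(rbind, lapply(seq_along(dk$curves), function(i)
      cbind(gene = sprintf("curve%04d", i), dk$curves[[i]])))
    fits <- decay_fit_table(long)
    state$decay <- list(sim = dk, fits = fits)
    write_result_tsv(fits, file.path(out_dir, "decay_fits.tsv"), cfg$decay)
  }

  writeLines(flatten_params(cfg), file.path(out_dir, "params_echo.txt"))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(state)
}

parse_cli_args <- function(args) {
  out <- list(flags = list(), subcommand = NULL)
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i == length(args) || startsWith(args[i + 1], "--"))
        stop("CLI: flag --", key, " needs a value")
      out$flags[[gsub("-", "_", key)]] <- args[i + 1]
      i <- i + 2
    } else {
      if (!is.null(out$subcommand)) stop("CLI: multiple subcommands")
      out$subcommand <- a
      i <- i + 1
    }
  }
  out
}

#' Command-line entry point
#'
#' Subcommands `simulate`, `quantify`, `landscape`, `inherit`, `cluster`,
#' `de`, `decay` run a single stage (with its upstream dependencies when
#' they are not on disk); `all` runs the full pipeline.  Global flags:
#' `--config <json>`, `--seed <int>`, `--out-dir <dir>`, `--log-level
#' <level>`.  See `inst/scripts/m6atlas` for the Rscript wrapper.
#'
#' @param args character vector of CLI arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return integer exit status, invisibly (0 = success).
#' @export
m6a_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    parsed <- parse_cli_args(args)
    sub <- parsed$subcommand
    if (is.null(sub))
      stop("usage: m6atlas <all|simulate|quantify|landscape|inherit|",
           "cluster|de|decay> [--config f] [--seed n] [--out-dir d]")
    cfg <- if (!is.null(parsed$flags$config))
      jsonlite::read_json(parsed$flags$config, simplifyVector = TRUE) else list()
    stage_sets <- list(
      all = default_config()$stages,
      simulate = "simulate",
      quantify = c("simulate", "quantify"),
      landscape = c("simulate", "quantify", "landscape"),
      inherit = c("simulate", "quantify", "landscape", "inherit"),
      cluster = c("simulate", "quantify", "landscape", "cluster"),
      de = c("simulate", "quantify", "landscape", "de"),
      decay = "decay")
    if (!sub %in% names(stage_sets)) stop("CLI: unknown subcommand ", sub)
    # external inputs replace the simulate stage when supplied
    if (!is.null(cfg$inputs$counts))
      stage_sets <- lapply(stage_sets, setdiff, "simulate")
    cfg$stages <- stage_sets[[sub]]
    seed <- if (!is.null(parsed$flags$seed))
      as.integer(parsed$flags$seed) else NULL
    out_dir <- if (!is.null(parsed$flags$out_dir))
      parsed$flags$out_dir else "m6atlas_out"
    run_pipeline(cfg, out_dir, seed)
    0L
  }, error = function(e) {
    message("m6atlas error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
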