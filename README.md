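# m6atlas

Meta-epitranscriptomic m6A landscapes along developmental hierarchies.

## What this is for

N6-methyladenosine (m6A) is the most abundant internal mRNA modification;
where it sits on the transcriptome differs between cell types and shifts as
stem cells commit to downstream lineages. Low-input m6A sequencing
protocols (MeRIP/SLIM-seq style) produce, for each sorted cell population,
a pair of gene-level count libraries: an antibody-immunoprecipitated (IP)
fraction enriched for methylated transcripts and a matched input fraction.
`m6atlas` turns a stack of such paired count matrices — e.g. eight FACS-sorted
populations of the skeletal stem-cell hierarchy, two biological replicates
each — into a quantitative, comparable m6A landscape, and then asks the
downstream questions: where along the hierarchy is each mark first
established, how does methylation relate to expression, which
knockout-responsive genes are methylated, and how stable are the
transcripts.

It is aimed at epitranscriptomics groups who already have gene-level counts
(featureCounts-style) and want a tested, deterministic, scriptable analysis
rather than a pile of one-off notebooks.

## The statistics at the core

* **Enrichment per gene and population.** For each population, IP vs input
  counts are compared with a negative-binomial Wald test:
  counts K_gj ~ NB(mu_gj, alpha_g) with log mu_gj = beta0_g + beta1_g x_j +
  log s_j, where x_j indicates IP, s_j are median-of-ratios size factors and
  alpha_g is a per-gene dispersion (variance mu + alpha mu^2) estimated by
  trend-floored method of moments. The Wald statistic W_g = log2FC_g /
  se_g is the per-gene evidence of methylation.
* **Relative m6A level.** Within a population, z_g = (W_g − mean W) / sd W
  (population SD). High-confidence **m6A targets** are genes with
  log2FC > 1 and P < 0.05 (both strict).
* **Inheritance.** Given a rooted population tree, a non-root target is
  *inherited* if the same gene is a target in an upstream population
  (immediate parent, or any ancestor — configurable), otherwise *de novo*;
  root targets form the *root set*.
* **Integration.** Complete-case genes are clustered (K-means, k-means++
  seeding, deterministic restarts) on concatenated mean-centered m6A and
  log2-expression profiles; each cluster gets a Pearson correlation sign
  between its mean m6A and mean expression profiles, and gene sets are
  scored with an upper-tail hypergeometric test.
* **Decay kinetics.** Transcription-arrest time courses are fit to
  ln(C/C0) = −K_decay t (least squares through the origin);
  t1/2 = ln2 / K_decay. MeRIP/RT-qPCR is quantified by 2^(−ddCt).

A seeded synthetic-data generator (`simulate_landscape_counts`,
`simulate_de_counts`, `simulate_decay`) plants ground truth for every one of
these stages; all statistical claims in the test suite are checked against
planted truth or independent oracles.

## Worked example

An end-to-end run on the default synthetic world (8 skeletal populations
SSC → pBCSP → BCSP → {PCP, Thy, BLSP, 6C3, HEC}, 2000 genes, 30% of genes
methylated at the root, planted enrichment log2FC = 2, NB dispersion 0.1,
2 replicates per assay):

```r
library(m6atlas)

sp   <- simulation_params(n_genes = 2000, seed = 7)
sim  <- simulate_landscape_counts(sp)
res  <- quantify_all(sim$counts, sim$samples)   # 8 IP-vs-input Wald tests
land <- assemble_landscape(res)
land
#> m6a_landscape: 2000 genes x 8 populations, 1200 union targets

stage_fractions(classify_inheritance(land, default_tree()))
#>   population n_targets frac_root_set frac_inherited frac_de_novo
#> 1        SSC       431             1          0.000        0.000
#> 2      pBCSP       455             0          0.571        0.429
#> 3       BCSP       514             0          0.708        0.292
#> 4        PCP       459             0          0.765        0.235
#> ...
```

1200 of 2000 genes are called a target in at least one population; per
population, the bar-plot-ready origin fractions say how much of each
stage's methylome was already present upstream. (The recovered inherited
fractions sit below the planted transition probability because inheritance
requires the gene to be *called* upstream; the acceptance suite checks the
recovery quantitatively after correcting for call sensitivity.)

```r
expr <- population_expression(sim$counts, sim$samples)
X    <- build_feature_matrix(land, expr, union_targets(land))
cl   <- kmeans_cluster(X, K = 2, seed = 7)
cl
#> cluster_assignment: K = 2, n = 1197, inertia = 1.75e+04
cluster_correlation_sign(cl, land$z[rownames(X), ], expr[rownames(X), ])
#>   cluster n_genes      r sign  p_value flag
#> 1       1     599 -0.970   -1 6.83e-05
#> 2       2     598 -0.944   -1 4.14e-04
```

(The default generator plants no m6A–expression coupling, so the
correlation signs here are incidental; planted-coupling recovery is
exercised in the test suite.)

```r
decay_fit(c(0, 2, 4, 8), c(1, 0.62, 0.41, 0.16))
#> decay_fit: k = 0.2284 /h, t1/2 = 3.035 h, r^2 = 0.9998 (ok)
```

The same pipeline is scriptable: `run_pipeline(config, out_dir, seed)` (or
the `inst/scripts/m6atlas` CLI with subcommands `simulate`, `quantify`,
`landscape`, `inherit`, `cluster`, `de`, `decay`, `all`) writes every stage's
table as diff-able commented TSV and is byte-identical across runs at a
fixed seed.

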