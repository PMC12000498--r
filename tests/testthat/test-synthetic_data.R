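test_that("landscape generator is seed-deterministic and truth is consistent", {
  sp <- simulation_params(n_genes = 400, mean_depth = 30, seed = 5)
  a <- simulate_landscape_counts(sp)
  b <- simulate_landscape_counts(sp)
  expect_identical(unclass(a$counts), unclass(b$counts))
  expect_identical(a$truth, b$truth)

  tr <- sp$tree
  truth <- a$truth
  # origin labels respect the generative rules
  expect_true(all(truth$origin[truth$population == tr$root &
                                 truth$methylated] == "root_set"))
  expect_true(all(truth$origin != "root_set" |
                    truth$population == tr$root))
  expect_identical(truth$methylated, truth$true_lfc > 0)
  parent_meth <- function(g, pop) {
    par <- tr$parent[[pop]]
    truth$methylated[truth$gene == g & truth$population == par]
  }
  inh <- truth[truth$origin == "inherited", ][1:20, ]
  expect_true(all(mapply(parent_meth, inh$gene, inh$population)))
  dnv <- truth[truth$origin == "de_novo", ][1:20, ]
  expect_false(any(mapply(parent_meth, dnv$gene, dnv$population)))
})

test_that("forced transition rules hold at the probability extremes", {
  tr <- chain_tree(c("SSC", "pBCSP", "BCSP"))
  sp <- simulation_params(n_genes = 300, tree = tr, frac_methylated_root = 0.5,
                          p_inherit = 1, p_denovo = 0, seed = 2)
  sim <- simulate_landscape_counts(sp)
  nonroot <- sim$truth[sim$truth$population != "SSC" & sim$truth$methylated, ]
  expect_true(all(nonroot$origin == "inherited"))
})

test_that("methylation propagation matches p_inherit / p_denovo (binomial CI)", {
  tr <- chain_tree(c("SSC", "pBCSP"))
  sp <- simulation_params(n_genes = 6000, tree = tr, frac_methylated_root = 0.4,
                          p_inherit = 0.8, p_denovo = 0.1, mean_depth = 20,
                          n_reps = 1, seed = 9)
  sim <- simulate_landscape_counts(sp)
  w <- reshape(sim$truth[, c("gene", "population", "methylated")],
               idvar = "gene", timevar = "population", direction = "wide")
  par_m <- w$methylated.SSC
  child_m <- w$methylated.pBCSP
  for (case in list(list(sel = par_m, p = 0.8), list(sel = !par_m, p = 0.1))) {
    n <- sum(case$sel)
    frac <- mean(child_m[case$sel])
    expect_lt(abs(frac - case$p), 3 * sqrt(case$p * (1 - case$p) / n))
  }
})

test_that("INPUT count moments follow the NB variance function", {
  tr <- chain_tree(c("A", "B"))
  sp <- simulation_params(n_genes = 150, tree = tr, mean_depth = 40,
                          dispersion = 0.2, n_reps = 80, seed = 4)
  sim <- simulate_landscape_counts(sp)
  in_ids <- sim$samples$sample_id[sim$samples$population == "A" &
                                    sim$samples$assay == "INPUT"]
  y <- sweep(unclass(sim$counts)[, in_ids], 2, sim$size_factors[in_ids], "/")
  mu <- rowMeans(y)
  # normalized counts: Var(K/s) = mu/s + alpha mu^2; use the realized mean 1/s
  c_inv <- mean(1 / sim$size_factors[in_ids])
  expected <- mu * c_inv + 0.2 * mu^2
  ratio <- apply(y, 1, var) / expected
  expect_lt(abs(mean(ratio) - 1), 0.1)
})

test_that("DE generator plants balanced signed effects and respects frac_de", {
  null_sim <- simulate_de_counts(n_genes = 200, frac_de = 0, seed = 3)
  expect_true(all(null_sim$truth$direction == "null"))

  sim <- simulate_de_counts(n_genes = 4000, frac_de = 0.05, lfc_de = 1, seed = 6)
  n_up <- sum(sim$truth$direction == "up")
  n_dn <- sum(sim$truth$direction == "down")
  sd_bin <- sqrt(4000 * 0.025 * 0.975)
  expect_lt(abs(n_up - 100), 3 * sd_bin)
  expect_lt(abs(n_dn - 100), 3 * sd_bin)

  again <- simulate_de_counts(n_genes = 4000, frac_de = 0.05, lfc_de = 1, seed = 6)
  expect_identical(unclass(sim$counts), unclass(again$counts))
})

test_that("decay generator hits the closed form and validates input", {
  noiseless <- simulate_decay(true_half_life_h = 2, times_h = c(0, 2, 4),
                              noise_sd = 0, n_curves = 1, seed = 1)
  expect_equal(noiseless$curves[[1]]$rel_abundance, c(1, 0.5, 0.25))

  noisy <- simulate_decay(3, c(0, 1, 3, 6), noise_sd = 0.1, n_curves = 3, seed = 8)
  expect_true(all(vapply(noisy$curves,
                         function(cv) cv$rel_abundance[cv$time_h == 0] == 1,
                         TRUE)))
  again <- simulate_decay(3, c(0, 1, 3, 6), noise_sd = 0.1, n_curves = 3, seed = 8)
  expect_identical(noisy$curves, again$curves)

  expect_error(simulate_decay(true_half_life_h = 0), "half-life")
  expect_error(simulate_decay(3, times_h = c(1, 2)), "include 0")
  expect_error(simulation_params(dispersion = -1), "dispersion")
  expect_error(simulation_params(p_inherit = 1.2), "probabilities")
})
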