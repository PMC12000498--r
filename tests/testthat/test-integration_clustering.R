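fab_landscape_expr <- function(z, expr_log) {
  list(landscape = make_landscape(z, z > 1), expr = 2^expr_log)
}

test_that("feature matrix: shape, zero rows, channel variance identity", {
  pops <- paste0("P", 1:4)
  genes <- paste0("G", 1:6)
  set.seed(2)
  z <- matrix(rnorm(24), 6, 4, dimnames = list(genes, pops))
  z["G1", ] <- 0.7                        # constant in both channels
  expr_log <- matrix(rnorm(24, 8), 6, 4, dimnames = list(genes, pops))
  expr_log["G1", ] <- 8
  fx <- fab_landscape_expr(z, expr_log)
  X <- build_feature_matrix(fx$landscape, fx$expr)
  expect_equal(ncol(X), 2 * length(pops))
  expect_equal(unname(X["G1", ]), rep(0, 8))
  expect_equal(mean(X[, 1:4]^2), 1, tolerance = 1e-9)
  expect_equal(mean(X[, 5:8]^2), 1, tolerance = 1e-9)

  z_na <- z; z_na["G2", "P1"] <- NA
  fx2 <- fab_landscape_expr(z_na, expr_log)
  X2 <- build_feature_matrix(fx2$landscape, fx2$expr)
  expect_false("G2" %in% rownames(X2))    # complete cases only
})

test_that("k-means: trivial K, duplicates, determinism, restarts, errors", {
  set.seed(14)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(paste0("G", 1:20), NULL))
  one <- kmeans_cluster(X, 1, seed = 1)
  expect_true(all(one$cluster == 1))
  expect_equal(one$inertia, sum(scale(X, scale = FALSE)^2), tolerance = 1e-9)

  Xdup <- rbind(X, X[3, , drop = FALSE])
  rownames(Xdup)[21] <- "Gdup"
  cl <- kmeans_cluster(Xdup, 4, seed = 2)
  expect_equal(unname(cl$cluster["Gdup"]), unname(cl$cluster["G3"]))

  a <- kmeans_cluster(X, 3, seed = 7)
  b <- kmeans_cluster(X, 3, seed = 7)
  expect_identical(a$cluster, b$cluster)
  expect_equal(a$inertia, b$inertia)

  # labels are 1..K ordered by descending size
  sizes <- table(a$cluster)
  expect_true(all(diff(as.numeric(sizes)) <= 0))

  # more restarts can only improve (or match) the kept inertia
  i1 <- kmeans_cluster(X, 3, seed = 5, n_init = 1)$inertia
  i10 <- kmeans_cluster(X, 3, seed = 5, n_init = 10)$inertia
  expect_lte(i10, i1 + 1e-9)

  expect_error(kmeans_cluster(X, 0), "K")
  expect_error(kmeans_cluster(X, 21), "exceeds")
})

test_that("adjusted Rand index behaves at the reference points", {
  a <- rep(1:2, each = 10)
  expect_equal(adjusted_rand_index(a, a), 1)
  expect_equal(adjusted_rand_index(a, 3 - a), 1)    # label permutation
  expect_equal(adjusted_rand_index(rep(1, 10), rep(1, 10)), 1)
  set.seed(3)
  expect_lt(abs(adjusted_rand_index(sample(1:2, 4000, TRUE),
                                    sample(1:2, 4000, TRUE))), 0.08)
})

test_that("cluster correlation sign recovers exact and negated profiles", {
  pops <- paste0("P", 1:5)
  genes <- paste0("G", 1:8)
  prof <- c(2, 1, 0, -1, -2)
  z <- matrix(rep(prof, each = 8), 8, 5, dimnames = list(genes, pops))
  expr_pos <- 2^(8 + z)                     # log2(expr) tracks z exactly
  assign <- structure(list(cluster = setNames(rep(1L, 8), genes), K = 1L,
                           seed = 1, n_init = 1, inertia = 0,
                           centers = NULL), class = "cluster_assignment")
  cc <- cluster_correlation_sign(assign, z, 8 + z, log_expression = FALSE)
  expect_equal(cc$r, 1, tolerance = 1e-9)
  expect_equal(cc$sign, 1)
  # through the default log2(x+1) transform the sign is still recovered
  cc_log <- cluster_correlation_sign(assign, z, expr_pos)
  expect_gt(cc_log$r, 0.99)

  cc2 <- cluster_correlation_sign(assign, z, 8 - z, log_expression = FALSE)
  expect_equal(cc2$r, -1, tolerance = 1e-9)

  z_flat <- matrix(1, 8, 5, dimnames = list(genes, pops))
  cc3 <- cluster_correlation_sign(assign, z_flat, expr_pos)
  expect_identical(cc3$flag, "zero_variance")
  expect_true(is.na(cc3$r))
})

test_that("hypergeometric enrichment is exact and handles edge cases", {
  universe <- paste0("G", 1:10)
  coll <- gene_set_collection(list(s = universe[1:5]))
  res <- hypergeometric_enrichment(universe[1:5], coll, universe)
  expect_equal(res$p_value, 1 / choose(10, 5), tolerance = 1e-12)

  res0 <- hypergeometric_enrichment(character(0), coll, universe)
  expect_equal(res0$overlap_k, 0)
  expect_equal(res0$p_value, 1)

  all_ann <- gene_set_collection(list(everything = universe))
  expect_equal(hypergeometric_enrichment(universe[1:3], all_ann,
                                         universe)$p_value, 1)

  expect_error(hypergeometric_enrichment("X1", coll, universe), "universe")

  # exhaustive enumeration oracle for small N
  set.seed(19)
  for (i in 1:4) {
    N <- sample(8:12, 1)
    uni <- paste0("u", 1:N)
    K <- sample(2:(N - 2), 1)
    n <- sample(2:(N - 2), 1)
    ann <- sample(uni, K)
    sel <- sample(uni, n)
    k_obs <- length(intersect(ann, sel))
    draws <- combn(N, n)
    ann_idx <- match(ann, uni)
    tail_count <- sum(apply(draws, 2,
                            function(d) sum(d %in% ann_idx) >= k_obs))
    p_exact <- tail_count / ncol(draws)
    got <- hypergeometric_enrichment(sel, gene_set_collection(list(s = ann)),
                                     uni)
    expect_equal(got$p_value, p_exact, tolerance = 1e-12)
  }
})
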