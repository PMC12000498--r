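test_that("size factors: symmetry, exact doubling, zero-gene exclusion", {
  m <- make_counts(matrix(c(10L, 10L, 20L, 20L, 5L, 5L), 3, 2, byrow = TRUE))
  expect_equal(unname(size_factors(m)), c(1, 1))

  a <- c(10L, 20L, 30L, 40L)
  m2 <- make_counts(cbind(A = a, B = 2L * a), samples = c("A", "B"))
  expect_equal(unname(size_factors(m2)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)

  with_zero <- make_counts(rbind(cbind(A = a, B = 2L * a), c(0L, 0L)))
  expect_equal(unname(size_factors(with_zero)), unname(size_factors(m2)))

  all_zero_somewhere <- make_counts(matrix(c(0L, 1L, 1L, 0L), 2, 2))
  expect_error(size_factors(all_zero_somewhere), "filter")
})

test_that("dispersion: stated moments formula at the boundaries", {
  # mean 10, variance 10 -> Poisson boundary
  y1 <- c(6L, 8L, 10L, 12L, 14L)
  # mean 10, variance 30 -> alpha 0.2
  y2 <- c(4L, 6L, 10L, 12L, 18L)
  m <- make_counts(rbind(y1, y2, rep(0L, 5)), genes = c("pois", "od", "zero"))
  d <- estimate_dispersion(m, rep("g", 5), rep(1, 5), shrink = FALSE)
  expect_equal(unname(d["pois"]), 0)
  expect_equal(unname(d["od"]), 0.2)
  expect_equal(unname(d["zero"]), 0)
  # shrunken estimate never drops below the stratum trend
  ds <- estimate_dispersion(m, rep("g", 5), rep(1, 5))
  expect_true(all(ds >= 0))
})

test_that("Wald test: symmetry, exact two-group ratio, zero-group handling", {
  m <- make_counts(matrix(c(15L, 15L, 15L, 15L), 1, 4), genes = "G1")
  groups <- factor(c("INPUT", "INPUT", "IP", "IP"), levels = c("INPUT", "IP"))
  res <- nb_wald_test(m, groups, rep(1, 4), c(G1 = 0.1))
  expect_equal(res$log2fc, 0, tolerance = 1e-9)
  expect_equal(res$wald_stat, 0, tolerance = 1e-9)
  expect_equal(res$p_value, 1, tolerance = 1e-9)

  m2 <- make_counts(matrix(c(10L, 10L, 20L, 20L), 1, 4), genes = "G1")
  res2 <- nb_wald_test(m2, groups, rep(1, 4), c(G1 = 0))
  expect_equal(res2$log2fc, 1, tolerance = 1e-8)
  expect_equal(res2$wald_stat, res2$log2fc / res2$se, tolerance = 1e-9)

  m3 <- make_counts(matrix(c(0L, 0L, 20L, 20L), 1, 4), genes = "G1")
  res3 <- nb_wald_test(m3, groups, rep(1, 4), c(G1 = 0.1))
  expect_identical(res3$flag, "zero_group")
  expect_true(is.finite(res3$log2fc) && res3$log2fc > 0)

  # low-count filter removes the gene from the universe
  m4 <- make_counts(matrix(c(1L, 0L, 2L, 1L, 50L, 40L, 60L, 55L), 2, 4,
                           byrow = TRUE), genes = c("low", "hi"))
  res4 <- nb_wald_test(m4, groups, rep(1, 4), c(low = 0.1, hi = 0.1),
                       min_total_count = 10)
  expect_identical(res4$gene, "hi")
})

test_that("scale invariance: count scaling absorbed by the size factor", {
  set.seed(31)
  m <- make_counts(matrix(rpois(40, 30), 10, 4))
  groups <- factor(rep(c("INPUT", "IP"), each = 2), levels = c("INPUT", "IP"))
  sf <- rep(1, 4)
  m_scaled <- unclass(m)
  m_scaled[, 3] <- m_scaled[, 3] * 3L
  sf2 <- sf; sf2[3] <- 3
  # exact for single-replicate groups, where the group MLE is y/s
  d0 <- setNames(rep(0, 10), rownames(m))
  g11 <- factor(c("INPUT", "IP"), levels = c("INPUT", "IP"))
  base11 <- nb_wald_test(count_matrix(unclass(m)[, c(1, 3)]), g11,
                         sf[c(1, 3)], d0, min_total_count = 0)
  scaled11 <- nb_wald_test(count_matrix(m_scaled[, c(1, 3)]), g11,
                           sf2[c(1, 3)], d0, min_total_count = 0)
  # the spec's invariant names log2fc only: scaled counts fake extra
  # Fisher information, so the standard error (and Wald stat) do change
  expect_equal(scaled11$log2fc, base11$log2fc, tolerance = 1e-6)
  # with >1 sample per group the rescaled sample carries more weight in
  # the pooled group estimate, so invariance is only approximate
  d1 <- setNames(rep(0.1, 10), rownames(m))
  base_nb <- nb_wald_test(m, groups, sf, d1, min_total_count = 0)
  scaled_nb <- nb_wald_test(count_matrix(m_scaled), groups, sf2, d1,
                            min_total_count = 0)
  expect_equal(scaled_nb$log2fc, base_nb$log2fc, tolerance = 0.1)
})

test_that("Poisson limit matches a brute-force Poisson GLM", {
  set.seed(17)
  for (rep in 1:5) {
    n_s <- sample(3:4, 1)
    x <- c(0, rep(1, n_s - 1))[sample(n_s)]
    if (length(unique(x)) < 2) x[1] <- 1 - x[1]
    sf <- runif(n_s, 0.6, 1.6)
    m <- make_counts(matrix(rpois(5 * n_s, 25 * sf), 5, n_s, byrow = TRUE))
    groups <- factor(ifelse(x == 1, "IP", "INPUT"), levels = c("INPUT", "IP"))
    disp <- setNames(rep(0, 5), rownames(m))
    mine <- nb_wald_test(m, groups, sf, disp, min_total_count = 0)
    for (g in mine$gene) {
      y <- unclass(m)[g, ]
      ref <- glm(y ~ x, family = poisson(), offset = log(sf))
      co <- summary(ref)$coefficients
      expect_equal(mine$log2fc[mine$gene == g], co["x", "Estimate"] / log(2),
                   tolerance = 1e-4)
      expect_equal(mine$wald_stat[mine$gene == g],
                   co["x", "Estimate"] / co["x", "Std. Error"],
                   tolerance = 1e-4)
    }
  }
})

test_that("BH adjustment matches the step-up rule and reference", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_equal(benjamini_hochberg(rep(1, 4)), rep(1, 4))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(8)
  for (i in 1:5) {
    p <- runif(sample(2:50, 1))
    expect_equal(benjamini_hochberg(p), p.adjust(p, "BH"))
  }
})
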