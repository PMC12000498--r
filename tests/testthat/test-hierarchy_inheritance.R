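land_from_targets <- function(tgt) {
  z <- tgt * 1.0
  make_landscape(z, tgt)
}

test_that("classification follows the upstream-evidence rules", {
  pops <- c("SSC", "pBCSP", "BCSP")
  tr <- chain_tree(pops)
  tgt <- matrix(FALSE, 3, 3, dimnames = list(c("G1", "G2", "G3"), pops))
  tgt["G1", c("SSC", "pBCSP")] <- TRUE         # inherited from SSC
  tgt["G2", "BCSP"] <- TRUE                    # leaf-only: de novo
  tgt["G3", c("SSC", "BCSP")] <- TRUE          # skips pBCSP
  land <- land_from_targets(tgt)

  any_anc <- classify_inheritance(land, tr, "any_ancestor")
  row <- function(tab, p, g) tab[tab$population == p & tab$gene == g, ]
  expect_identical(row(any_anc, "pBCSP", "G1")$origin, "inherited")
  expect_identical(row(any_anc, "pBCSP", "G1")$evidence, "SSC")
  expect_identical(row(any_anc, "BCSP", "G2")$origin, "de_novo")
  expect_identical(row(any_anc, "BCSP", "G3")$origin, "inherited")
  expect_identical(row(any_anc, "BCSP", "G3")$evidence, "SSC")
  expect_identical(row(any_anc, "SSC", "G1")$origin, "root_set")

  par_mode <- classify_inheritance(land, tr, "parent")
  expect_identical(row(par_mode, "BCSP", "G3")$origin, "de_novo")

  bad <- make_landscape(matrix(0, 1, 1, dimnames = list("G1", "Unknown")),
                        matrix(TRUE, 1, 1, dimnames = list("G1", "Unknown")))
  expect_error(classify_inheritance(bad, tr), "not in tree")
})

test_that("missing (unscored) ancestor cells count as absent", {
  pops <- c("SSC", "pBCSP")
  tr <- chain_tree(pops)
  tgt <- matrix(c(NA, TRUE), 1, 2, dimnames = list("G1", pops))
  land <- make_landscape(tgt * 1.0, tgt)
  tab <- classify_inheritance(land, tr)
  expect_identical(tab$origin, "de_novo")
})

test_that("stage fractions: arithmetic, root convention, zero-target NA", {
  pops <- c("SSC", "pBCSP", "BCSP")
  tr <- chain_tree(pops)
  tgt <- matrix(FALSE, 5, 3, dimnames = list(paste0("G", 1:5), pops))
  tgt[c("G1", "G2", "G3", "G4"), "SSC"] <- TRUE
  tgt[c("G1", "G2", "G3"), "pBCSP"] <- TRUE     # 3 inherited
  tgt["G5", "pBCSP"] <- TRUE                    # 1 de novo
  land <- land_from_targets(tgt)
  fr <- stage_fractions(classify_inheritance(land, tr))
  expect_equal(fr$frac_inherited[fr$population == "pBCSP"], 0.75)
  expect_equal(fr$frac_de_novo[fr$population == "pBCSP"], 0.25)
  expect_equal(fr$frac_root_set[fr$population == "SSC"], 1)
  expect_true(is.na(fr$frac_inherited[fr$population == "BCSP"]))
  expect_equal(fr$n_targets[fr$population == "BCSP"], 0L)
})

test_that("group aggregation is the target-weighted pooled fraction", {
  pops <- c("R", "A", "B")
  tr <- hierarchy_tree(data.frame(parent = c("R", "R"), child = c("A", "B")))
  genes <- paste0("G", 1:40)
  tgt <- matrix(FALSE, 40, 3, dimnames = list(genes, pops))
  # A: 10 targets, 6 inherited; B: 30 targets, 21 inherited
  tgt[1:6, "R"] <- TRUE; tgt[1:10, "A"] <- TRUE
  tgt[11:31, "R"] <- TRUE; tgt[11:40, "B"] <- TRUE
  land <- land_from_targets(tgt)
  tab <- classify_inheritance(land, tr, "parent")
  agg <- aggregate_group_fraction(tab, c("A", "B"), "inherited")
  expect_equal(agg$pooled, 27 / 40)
  expect_equal(unname(agg$per_population), c(0.6, 0.7))
  expect_equal(agg$max, 0.7)
  single <- aggregate_group_fraction(tab, "A", "inherited")
  expect_equal(single$pooled,
               stage_fractions(tab)$frac_inherited[
                 stage_fractions(tab)$population == "A"])
  expect_equal(aggregate_group_fraction(tab, "A", "root_set")$pooled, 0)
})

test_that("partition and mode-monotonicity invariants hold on random landscapes", {
  set.seed(41)
  trees <- all_rooted_trees(4)
  for (i in seq(1, length(trees), by = 9)) {
    tr <- hierarchy_tree(trees[[i]])
    genes <- paste0("G", 1:15)
    tgt <- matrix(runif(15 * length(tr$nodes)) < 0.4, 15,
                  length(tr$nodes), dimnames = list(genes, tr$nodes))
    land <- land_from_targets(tgt)
    tab_p <- classify_inheritance(land, tr, "parent")
    tab_a <- classify_inheritance(land, tr, "any_ancestor")
    fr_p <- stage_fractions(tab_p)
    fr_a <- stage_fractions(tab_a)
    nonroot <- fr_p$population != tr$root & fr_p$n_targets > 0
    expect_equal(fr_p$frac_inherited[nonroot] + fr_p$frac_de_novo[nonroot],
                 rep(1, sum(nonroot)))
    expect_true(all(fr_a$frac_inherited[nonroot] >=
                      fr_p$frac_inherited[nonroot]))
  }
})
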