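# Synthetic-data generators: trees, categories, traits, sequences, bundles.

test_that("simulated trees are ultrametric at the requested root age", {
  two <- simulate_tree(2, seed = 1)
  d2 <- ape::node.depth.edgelength(two)[1:2]
  expect_equal(d2, c(110, 110))
  tr <- simulate_tree(134, root_age = 110, seed = 2)
  depths <- ape::node.depth.edgelength(tr)[1:134]
  expect_equal(depths, rep(110, 134), tolerance = 1e-9)
  expect_identical(write_newick(simulate_tree(20, seed = 9)),
                   write_newick(simulate_tree(20, seed = 9)))
  expect_error(simulate_tree(1), class = "phyloprior_validation_error")
})

test_that("category assignment follows the requested frequencies", {
  tips <- sprintf("t%d", 1:1350)
  all_lc <- simulate_categories(tips, c(LC = 1), seed = 1)
  expect_true(all(all_lc == "LC"))
  cats <- simulate_categories(tips, seed = 3)
  n_cr <- sum(cats == "CR")
  p <- 35 / 135
  se3 <- 3 * sqrt(1350 * p * (1 - p))
  expect_lt(abs(n_cr - 1350 * p), se3)
  expect_error(simulate_categories(tips, c(LC = 0.5, CR = 0.4)),
               class = "phyloprior_validation_error")
})

test_that("trait simulation hits the target rank association", {
  tips <- sprintf("t%d", 1:500)
  ord_map <- c(LC = 1, NT = 2, VU = 3, EN = 4, CR = 5, RE = 6)
  hit <- function(target, s) {
    cats <- simulate_categories(tips, seed = 600 + s)
    tr <- simulate_traits(cats, target, prevalence = c(0.34, 0.66),
                          seed = 700 + s)
    cor(ord_map[cats], tr, method = "spearman", use = "complete.obs")
  }
  null_hits <- vapply(1:20, function(s) hit(0, s), numeric(1))
  expect_gte(mean(abs(null_hits) <= 0.1), 0.95)
  rec <- vapply(1:20, function(s) hit(0.55, s), numeric(1))
  expect_gte(mean(abs(rec - 0.55) <= 0.1), 0.95)
})

test_that("unattainable targets raise a calibration error", {
  cats <- simulate_categories(sprintf("t%d", 1:300), seed = 5)
  expect_error(simulate_traits(cats, 0.99, prevalence = c(0.98, 0.02),
                               seed = 5),
               class = "phyloprior_calibration_error")
  # a balanced binary trait can carry a high association
  expect_silent(simulate_traits(cats, 0.8, prevalence = c(0.5, 0.5),
                                seed = 5))
})

test_that("sequence simulation respects the intraspecific divergence dial", {
  tr <- simulate_tree(6, seed = 11)
  aln0 <- simulate_sequences(tr, marker_length = 300, intra_divergence = 0,
                             accessions_per_species = 2, seed = 12)
  md0 <- partition_distances(aln0)
  expect_true(all(md0$intra == 0))
  # kappa -> large: transversions vanish
  aln_k <- simulate_sequences(tr, marker_length = 4000, kappa = 2000,
                              accessions_per_species = 1, seed = 13)
  md_k <- partition_distances(aln_k)
  expect_lt(mean(md_k$pairs$Q), 0.002)
})

test_that("K2P estimates recover the generating scales", {
  b <- make_fixture(n_taxa = 30, accessions_per_species = 2,
                    marker_length = 10000, seed = 19)
  md <- partition_distances(b$alignment)
  expect_lt(abs(md$intra_mean - 0.003) / 0.003, 0.2)
  expect_lt(abs(md$inter_mean - 0.08) / 0.08, 0.35)
})

test_that("fixture bundles are deterministic and mutually consistent", {
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  b1 <- make_fixture(d1, n_taxa = 12, accessions_per_species = 2,
                     marker_length = 200, seed = 42)
  b2 <- make_fixture(d2, n_taxa = 12, accessions_per_species = 2,
                     marker_length = 200, seed = 42)
  for (f in names(b1$paths))
    expect_identical(readLines(b1$paths[[f]]), readLines(b2$paths[[f]]))
  # shared labels across files
  expect_setequal(b1$tree$tip.label, b1$assessments$taxon)
  expect_setequal(unique(unname(b1$alignment$species)), b1$tree$tip.label)
  # a small bundle runs the scoring pipeline end to end
  fit <- edge2(b1$tree, b1$assessments, scope = "hk", n_draws = 50, seed = 1)
  expect_equal(nrow(fit$scores), 12L)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("fixture traits carry a detectable habitat association", {
  hits <- vapply(1:10, function(s) {
    b <- make_fixture(n_taxa = 134, accessions_per_species = 1,
                      marker_length = 10, seed = 800 + s)
    out <- trait_threat_correlations(b$assessments, "hk",
                                     traits = "habitat_specificity")
    out$rho > 0 && out$p.value < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
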