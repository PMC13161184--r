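# K2P distances, the intra/inter partition, diversity decomposition, the
# barcoding-gap ANOVA, and the site bootstrap.

split1 <- function(s) strsplit(s, "")[[1]]

test_that("K2P distance matches its closed form", {
  expect_equal(k2p_distance(rep("A", 10), rep("A", 10))$d, 0)
  # 100 sites, 10 transitions, no transversions: d = -1/2 log(0.8)
  s1 <- rep("A", 100)
  s2 <- c(rep("G", 10), rep("A", 90))
  kd <- k2p_distance(s1, s2)
  expect_equal(kd$P, 0.1)
  expect_equal(kd$Q, 0)
  expect_equal(kd$d, -0.5 * log(0.8))
  # pairwise deletion drops gap/ambiguity sites
  kd2 <- k2p_distance(split1("ACGT"), split1("A-GT"))
  expect_equal(kd2$usable, 3L)
  kd3 <- k2p_distance(split1("ACGT"), split1("ANGT"))
  expect_equal(kd3$usable, 3L)
  expect_error(k2p_distance(split1("----"), split1("AAAA")),
               class = "phyloprior_data_error")
  expect_error(k2p_distance(split1("ACG"), split1("AC")),
               class = "phyloprior_validation_error")
})

test_that("saturated pairs are flagged undefined, not clamped", {
  # all sites transversions: Q = 1 -> both log arguments <= 0
  kd <- k2p_distance(rep("A", 20), rep("C", 20))
  expect_true(kd$saturated)
  expect_true(is.na(kd$d))
})

test_that("K2P agrees with an independent distance implementation", {
  b <- make_fixture(n_taxa = 8, accessions_per_species = 2,
                    marker_length = 300, seed = 5)
  md <- partition_distances(b$alignment)
  D <- as.matrix(ape::dist.dna(ape::as.DNAbin(tolower(b$alignment$seqs)),
                               model = "K80", pairwise.deletion = TRUE))
  ref <- mapply(function(a1, a2) D[a1, a2], md$pairs$acc1, md$pairs$acc2)
  expect_equal(unname(md$pairs$d), unname(ref), tolerance = 1e-12)
})

test_that("pair partition is complete and correctly labelled", {
  seqs <- rbind(a1 = split1("ACGTACGTAC"), a2 = split1("ACGTACGTAC"),
                b1 = split1("ACGAACGAAC"), b2 = split1("ACGAACGAAC"))
  sp <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  md <- partition_distances(marker_alignment(seqs, sp))
  expect_equal(length(md$intra), 2L)
  expect_equal(length(md$inter), 4L)
  expect_equal(length(md$intra) + length(md$inter) + md$n_undefined,
               choose(4, 2))
  # single accession per species: intra statistics absent, not zero
  md2 <- partition_distances(marker_alignment(
    rbind(a1 = split1("ACGT"), b1 = split1("ACGA")),
    c(a1 = "A", b1 = "B")))
  expect_length(md2$intra, 0L)
  expect_true(is.na(md2$intra_mean))
  expect_null(md2$diversity)
})

test_that("intra and inter scales separate on gap-structured data", {
  b <- make_fixture(n_taxa = 10, accessions_per_species = 3,
                    marker_length = 2000, seed = 17,
                    intra_divergence = 0.003)
  md <- partition_distances(b$alignment)
  expect_lt(max(md$intra), min(md$inter))
})

test_that("diversity decomposition reproduces the published identity", {
  dd <- diversity_decomposition(0.0480, 0.0038)
  expect_equal(dd$delta_between, 0.0442)
  expect_equal(diversity_decomposition(0.1297, 0.0070)$coefficient,
               0.9462, tolerance = 1e-3)
  expect_equal(diversity_decomposition(1, 0)$coefficient, 1)
  expect_error(diversity_decomposition(0, 0),
               class = "phyloprior_data_error")
  # identity holds on computed partitions too
  b <- make_fixture(n_taxa = 8, accessions_per_species = 2,
                    marker_length = 500, seed = 23)
  md <- partition_distances(b$alignment)
  dd2 <- diversity_decomposition(md)
  expect_equal(dd2$delta_between + dd2$pi_within, dd2$pi_total)
  expect_equal(dd2$coefficient, dd2$delta_between / dd2$pi_total)
})

test_that("barcoding-gap ANOVA matches a hand computation", {
  intra <- c(0.001, 0.002, 0.003)
  inter <- c(0.10, 0.11, 0.12)
  md <- structure(list(intra = intra, inter = inter),
                  class = "marker_distances")
  av <- barcoding_gap_anova(md)
  expect_equal(av$F, hand_anova_f(intra, inter))
  expect_lt(av$p.value, 0.01)
  # identical values in both groups: F = 0, p = 1
  md0 <- structure(list(intra = rep(0.01, 3), inter = rep(0.01, 3)),
                   class = "marker_distances")
  av0 <- barcoding_gap_anova(md0)
  expect_equal(av0$F, 0)
  expect_equal(av0$p.value, 1)
  md_empty <- structure(list(intra = numeric(0), inter = inter),
                        class = "marker_distances")
  expect_error(barcoding_gap_anova(md_empty),
               class = "phyloprior_data_error")
})

test_that("clearly separated scales give overwhelming ANOVA evidence", {
  b <- make_fixture(n_taxa = 10, accessions_per_species = 3,
                    marker_length = 1000, seed = 41)
  md <- partition_distances(b$alignment)
  expect_lt(barcoding_gap_anova(md)$p.value, 1e-6)
})

test_that("site bootstrap is seeded, zero on invariant data, and shrinks with length", {
  const <- marker_alignment(rbind(a1 = rep("A", 50), a2 = rep("A", 50),
                                  b1 = rep("A", 50)),
                            c(a1 = "A", a2 = "A", b1 = "B"))
  stat <- function(aln) {
    md <- partition_distances(aln)
    md$overall_mean
  }
  expect_equal(bootstrap_se(const, stat, replicates = 20, seed = 1), 0)
  b <- make_fixture(n_taxa = 6, accessions_per_species = 2,
                    marker_length = 200, seed = 3)
  se1 <- bootstrap_se(b$alignment, stat, replicates = 50, seed = 2)
  expect_identical(se1, bootstrap_se(b$alignment, stat, replicates = 50,
                                     seed = 2))
  blong <- make_fixture(n_taxa = 6, accessions_per_species = 2,
                        marker_length = 2000, seed = 3)
  se2 <- bootstrap_se(blong$alignment, stat, replicates = 50, seed = 2)
  expect_lt(se2, se1)
})
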