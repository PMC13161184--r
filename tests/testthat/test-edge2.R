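# The EDGE2 resampling pipeline, ranking, and the ED ~ threat regression.

test_that("EDGE2 draws obey the elementwise identity and bounds", {
  tr <- simulate_tree(15, seed = 4)
  tab <- toy_assessments(tr$tip.label,
                         rep(c("CR", "EN", "VU", "NT", "LC"), 3))
  fit <- edge2(tr, tab, scope = "hk", n_draws = 50, seed = 9)
  expect_equal(fit$edge2_draws, fit$ed2_draws * fit$ge2_draws)
  expect_true(all(fit$edge2_draws < fit$ed2_draws))
  expect_true(all(fit$edge2_draws > 0))
  expect_true(all(fit$scores$EDGE2_IQR >= 0))
})

test_that("a cherry with forced GE2 reproduces the direct product", {
  tr <- read_newick("(A:1,B:1);")
  tab <- toy_assessments(c("A", "B"), c("CR", "LC"))
  # degenerate pools: every pool value equals the category median
  model <- build_risk_model(pool_size = 3, seed = 1)
  model$pools <- lapply(c(CR = 0.97, EN = 0.485, VU = 0.2425,
                          NT = 0.12125, LC = 0.060625),
                        function(m) rep(m, 3))
  model$pooled <- unlist(model$pools, use.names = FALSE)
  fit <- edge2(tr, tab, scope = "hk", model = model, n_draws = 20, seed = 2)
  s <- fit$scores
  expect_equal(s$ED2_median, c(1, 1))   # no internal edges
  expect_equal(s$EDGE2_median[s$taxon == "A"], 0.97)
  expect_equal(s$EDGE2_median[s$taxon == "B"], 0.060625)
})

test_that("identical seeds give identical results; scope wiring works", {
  tr <- simulate_tree(12, seed = 5)
  tab <- assessment_table(data.frame(
    taxon = tr$tip.label,
    hk = rep(c("CR", "LC", "VU", "EN"), 3),
    cn = rep(c("LC", "LC", "NT", "VU"), 3)))
  f1 <- edge2(tr, tab, scope = "hk", n_draws = 100, seed = 7)
  f2 <- edge2(tr, tab, scope = "hk", n_draws = 100, seed = 7)
  expect_identical(f1$scores$EDGE2_median, f2$scores$EDGE2_median)
  expect_identical(f1$scores$EDGE2_IQR, f2$scores$EDGE2_IQR)
  f3 <- edge2(tr, tab, scope = "cn", n_draws = 100, seed = 7)
  expect_false(identical(f1$scores$EDGE2_median, f3$scores$EDGE2_median))
})

test_that("raising a taxon's category never lowers its EDGE2 median", {
  for (s in 1:5) {
    tr <- simulate_tree(10, seed = 300 + s)
    cats <- rep("NT", 10)
    ladder <- c("LC", "NT", "VU", "EN", "CR")
    meds <- vapply(ladder, function(cc) {
      cats2 <- cats; cats2[4] <- cc
      fit <- edge2(tr, toy_assessments(tr$tip.label, cats2),
                   scope = "hk", n_draws = 200, seed = 50 + s)
      fit$scores$EDGE2_median[4]
    }, numeric(1))
    expect_true(all(diff(meds) >= 0))
  }
})

test_that("all-LC scores are stochastically dominated by all-CR scores", {
  tr <- simulate_tree(8, seed = 31)
  lc <- edge2(tr, toy_assessments(tr$tip.label, rep("LC", 8)),
              scope = "hk", n_draws = 500, seed = 3)
  cr <- edge2(tr, toy_assessments(tr$tip.label, rep("CR", 8)),
              scope = "hk", n_draws = 500, seed = 3)
  expect_true(all(lc$scores$EDGE2_median < cr$scores$EDGE2_median))
})

test_that("missing tips in the assessment table are named in the error", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  tab <- toy_assessments(c("A", "B"), c("CR", "LC"))
  err <- tryCatch(edge2(tr, tab, n_draws = 5, seed = 1),
                  condition = identity)
  expect_s3_class(err, "phyloprior_validation_error")
  expect_match(conditionMessage(err), "C")
})

test_that("ranking is dense, tie-broken by ED2 then label", {
  tr <- simulate_tree(20, seed = 8)
  tab <- toy_assessments(tr$tip.label, rep("VU", 20))
  fit <- edge2(tr, tab, scope = "hk", n_draws = 50, seed = 2)
  top <- rank_top_n(fit, 100)          # larger than taxa count: full table
  expect_equal(nrow(top), 20L)
  expect_true(all(diff(top$EDGE2_median) <= 0))
  # synthetic tie: equal medians ordered by ED2 median, then label
  fit2 <- fit
  fit2$scores$EDGE2_median <- rep(1, 20)
  fit2$scores$ED2_median <- rep(c(2, 1), 10)
  t2 <- rank_top_n(fit2, 4)
  expect_true(all(diff(t2$ED2_median) <= 0))
  # a CR taxon with the highest ED2 ranks first
  tab3 <- toy_assessments(tr$tip.label, rep("LC", 20))
  fit3 <- edge2(tr, tab3, scope = "hk", n_draws = 100, seed = 3)
  big <- fit3$scores$taxon[which.max(fit3$scores$ED2_median)]
  cats4 <- rep("LC", 20); cats4[tr$tip.label == big] <- "CR"
  fit4 <- edge2(tr, toy_assessments(tr$tip.label, cats4),
                scope = "hk", n_draws = 100, seed = 3)
  expect_equal(rank_top_n(fit4, 1)$taxon, big)
})

test_that("histogram bins partition the score range", {
  tr <- simulate_tree(25, seed = 12)
  tab <- toy_assessments(tr$tip.label, rep(c("CR", "LC", "VU", "EN", "NT"), 5))
  fit <- edge2(tr, tab, scope = "hk", n_draws = 100, seed = 5)
  b <- edge2_bins(fit, width = 5)
  expect_equal(sum(b$count), 25L)
  expect_equal(b$bin_high - b$bin_low, rep(5, nrow(b)))
})

test_that("ED ~ threat regression matches closed-form OLS and handles edge cases", {
  taxa <- sprintf("t%d", 1:5)
  tab <- toy_assessments(taxa, c("LC", "NT", "VU", "EN", "CR"))
  reg <- ed_threat_regression(setNames(c(1, 2, 3, 4, 5), taxa), tab, "hk")
  expect_equal(reg$r.squared, 1)
  expect_lt(reg$p.value, 1e-6)

  ed <- setNames(c(2, 1, 4, 3, 6), taxa)
  reg2 <- ed_threat_regression(ed, tab, "hk")
  oracle <- hand_ols(0:4, c(2, 1, 4, 3, 6))
  expect_equal(reg2$slope, oracle$slope)       # 1.0
  expect_equal(reg2$intercept, oracle$intercept)
  expect_equal(reg2$r.squared, oracle$r2)

  regc <- ed_threat_regression(setNames(rep(2, 5), taxa), tab, "hk")
  expect_equal(regc$slope, 0)
  expect_equal(regc$r.squared, 0)

  # RE/DD taxa are excluded from the regression
  tab2 <- toy_assessments(sprintf("t%d", 1:6),
                          c("LC", "NT", "VU", "EN", "CR", "RE"))
  ed6 <- setNames(c(2, 1, 4, 3, 6, 100), sprintf("t%d", 1:6))
  reg3 <- ed_threat_regression(ed6, tab2, "hk")
  expect_equal(reg3$n, 5L)
  expect_equal(reg3$slope, oracle$slope)

  tab_all_lc <- toy_assessments(taxa, rep("LC", 5))
  expect_error(ed_threat_regression(ed, tab_all_lc, "hk"),
               class = "phyloprior_data_error")
  tab_few <- toy_assessments(taxa, c("LC", "NT", "RE", "DD", "NA"))
  expect_error(ed_threat_regression(ed, tab_few, "hk"),
               class = "phyloprior_data_error")
})
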