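# Independent oracles used across the tests.  These deliberately avoid the
# package's own incidence machinery: tip descent is recomputed by naive
# recursion, and expectations are taken by exhaustive enumeration.

# Descendant tip indices of the child node of each edge, by naive recursion.
naive_edge_descendants <- function(tree) {
  n <- length(tree$tip.label)
  desc_of <- function(node) {
    if (node <= n) return(node)
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, desc_of))
  }
  lapply(seq_len(nrow(tree$edge)), function(e) desc_of(tree$edge[e, 2]))
}

# Edge rows on the path from tip i to the root.
naive_root_path <- function(tree, i) {
  n <- length(tree$tip.label)
  root <- n + 1L
  path <- integer(0)
  node <- i
  while (node != root) {
    e <- which(tree$edge[, 2] == node)
    path <- c(path, e)
    node <- tree$edge[e, 1]
  }
  path
}

# Expected unique PD of every tip by exhaustive enumeration over all
# survival states of the other tips (each k goes extinct independently with
# probability p[k]); a branch counts toward tip i when every other
# descendant of that branch is extinct.  Exact for p in (0, 1).
enumerate_expected_unique_pd <- function(tree, p) {
  n <- length(tree$tip.label)
  p <- p[tree$tip.label]
  desc <- naive_edge_descendants(tree)
  sapply(seq_len(n), function(i) {
    others <- setdiff(seq_len(n), i)
    m <- length(others)
    path <- naive_root_path(tree, i)
    total <- 0
    for (mask in 0:(2^m - 1)) {
      extinct <- others[bitwAnd(mask, 2^(seq_len(m) - 1)) > 0]
      alive <- setdiff(others, extinct)
      prob <- prod(p[extinct]) * prod(1 - p[alive])
      contrib <- sum(vapply(path, function(e) {
        oth <- setdiff(desc[[e]], i)
        if (all(oth %in% extinct)) tree$edge.length[e] else 0
      }, numeric(1)))
      total <- total + prob * contrib
    }
    total
  })
}

# Closed-form OLS of y on x (slope, intercept, r2).
hand_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  fitted <- intercept + slope * x
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r2 = r2)
}

# Hand one-way ANOVA F for two groups.
hand_anova_f <- function(g1, g2) {
  d <- c(g1, g2)
  k <- 2
  n <- length(d)
  gm <- mean(d)
  ssb <- length(g1) * (mean(g1) - gm)^2 + length(g2) * (mean(g2) - gm)^2
  ssw <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)
  (ssb / (k - 1)) / (ssw / (n - k))
}

# A tiny deterministic assessment table for pipeline tests.
toy_assessments <- function(taxa, hk, cn = NULL) {
  assessment_table(data.frame(
    taxon = taxa, hk = hk,
    cn = if (is.null(cn)) hk else cn,
    stringsAsFactors = FALSE))
}
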