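# The EDGE2 resampling pipeline and its S3 interface.

#' EDGE2 conservation-priority scores with resampling uncertainty
#'
#' For each of \code{n_draws} iterations, every tip is assigned an extinction
#' probability (GE2) drawn from the pool matching its Red List category in
#' the chosen scope; ED2 is then computed for all tips under that joint
#' assignment, and \code{EDGE2 = ED2 * GE2}.  Per-taxon medians and
#' interquartile ranges over the draws summarize the scores, and taxa are
#' dense-ranked by descending EDGE2 median.
#'
#' The draws are joint: one GE2 value per taxon per iteration, because each
#' taxon's ED2 depends on the probabilities of all other taxa (its own never
#' enters its own ED2).  Each taxon consumes a fixed number of random
#' variates per run, so fixed-seed runs remain comparable when a single
#' taxon's category changes.
#'
#' @param tree a rooted dated \code{phylo}; every tip must have a row in
#'   \code{assessments}.
#' @param assessments an \code{\link{assessment_table}}.
#' @param scope \code{"hk"} (regional) or \code{"cn"} (national).
#' @param model a \code{\link{build_risk_model}} object; built on the fly
#'   (seeded from the run stream) when \code{NULL}.
#' @param n_draws number of resampling iterations (default 500).
#' @param seed optional RNG seed covering the whole run.
#' @param dd_method how DD/NE/NA taxa are sampled; see \code{\link{draw_ge2}}.
#' @param ed_method passed to \code{\link{fair_proportion_ed}}.
#' @return an object of class \code{edge2_fit}: a list with \code{scores}
#'   (data frame: taxon, category, ED, ED2 median/IQR, EDGE2 median/IQR,
#'   rank), draw matrices \code{ed2_draws}, \code{edge2_draws},
#'   \code{ge2_draws}, and the call metadata.
#' @seealso \code{\link{rank_top_n}}, \code{\link{edge2_bins}}
#' @export
#' @examples
#' tr <- read_newick("((A:10,B:10):5,(C:7,D:7):8);")
#' tab <- assessment_table(data.frame(
#'   taxon = c("A", "B", "C", "D"),
#'   hk = c("CR", "LC", "EN", "DD")))
#' fit <- edge2(tr, tab, scope = "hk", n_draws = 100, seed = 1)
#' fit$scores
edge2 <- function(tree, assessments, scope = c("hk", "cn"), model = NULL,
                  n_draws = 500L, seed = NULL,
                  dd_method = c("pooled", "uniform"),
                  ed_method = "fair.proportion") {
  scope <- match.arg(scope)
  dd_method <- match.arg(dd_method)
  n_draws <- as.integer(n_draws)
  if (is.na(n_draws) || n_draws < 1L)
    pp_validation_error("'n_draws' must be >= 1")
  idx <- tree_index(tree)
  cats <- scope_categories(assessments, scope, idx$tips)
  maybe_seed(seed)
  if (is.null(model)) model <- build_risk_model()
  stopifnot(inherits(model, "risk_model"))

  n <- idx$n_tip
  G <- matrix(0, nrow = n, ncol = n_draws,
              dimnames = list(idx$tips, NULL))
  for (i in seq_len(n))                      # fixed tip order, fixed stream use
    G[i, ] <- draw_ge2_stream(model, cats[[i]], n_draws, dd_method)

  ED2 <- ed2_from_index(idx, G)
  EDGE2 <- ED2 * G
  q <- function(M) t(apply(M, 1, quantile, probs = c(0.25, 0.5, 0.75),
                           names = FALSE))
  q2 <- q(ED2); qe <- q(EDGE2)
  med_edge2 <- qe[, 2]
  rank <- match(med_edge2, sort(unique(med_edge2), decreasing = TRUE))
  scores <- data.frame(
    taxon = idx$tips,
    category = unname(cats),
    ED = unname(fair_proportion_ed(tree, method = ed_method)),
    ED2_median = q2[, 2], ED2_IQR = q2[, 3] - q2[, 1],
    EDGE2_median = med_edge2, EDGE2_IQR = qe[, 3] - qe[, 1],
    rank = rank,
    stringsAsFactors = FALSE)
  structure(list(scores = scores,
                 ed2_draws = ED2, edge2_draws = EDGE2, ge2_draws = G,
                 tree = tree, scope = scope, n_draws = n_draws,
                 seed = seed, dd_method = dd_method,
                 pd = total_pd(tree),
                 call = match.call()),
            class = "edge2_fit")
}

#' @export
print.edge2_fit <- function(x, ...) {
  cat(sprintf("EDGE2 fit: %d taxa, scope '%s', %d draws\n",
              nrow(x$scores), x$scope, x$n_draws))
  cat(sprintf("total PD: %.2f Myr\n", x$pd))
  top <- head(x$scores[order(x$scores$rank), ], 5)
  cat("top 5 by EDGE2 median:\n")
  print(top[, c("taxon", "category", "EDGE2_median", "EDGE2_IQR", "rank")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.edge2_fit <- function(object, n = 10, ...) {
  s <- object$scores
  out <- list(n_taxa = nrow(s), scope = object$scope,
              n_draws = object$n_draws, pd = object$pd,
              ed_range = range(s$ED),
              edge2_range = range(s$EDGE2_median),
              top = rank_top_n(object, n),
              category_counts = table(s$category))
  class(out) <- "summary.edge2_fit"
  out
}

#' @export
print.summary.edge2_fit <- function(x, ...) {
  cat(sprintf("EDGE2 summary: %d taxa (scope '%s', %d draws)\n",
              x$n_taxa, x$scope, x$n_draws))
  cat(sprintf("total PD %.2f Myr; ED range %.2f-%.2f; EDGE2 median range %.3f-%.2f\n",
              x$pd, x$ed_range[1], x$ed_range[2],
              x$edge2_range[1], x$edge2_range[2]))
  print(x$top, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
as.data.frame.edge2_fit <- function(x, ...) x$scores

#' @export
plot.edge2_fit <- function(x, width = 5, main = NULL, ...) {
  b <- edge2_bins(x, width = width)
  graphics::barplot(b$count,
                    names.arg = sprintf("%g-%g", b$bin_low, b$bin_high),
                    xlab = "EDGE2 median (Myr)", ylab = "taxa",
                    main = main %||% sprintf("EDGE2 scores (scope '%s')",
                                             x$scope),
                    las = 2, ...)
  invisible(b)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Top-ranked taxa by EDGE2 median
#'
#' Descending by EDGE2 median; ties broken by ED2 median, then by taxon
#' label.
#'
#' @param fit an \code{edge2_fit}.
#' @param n number of rows requested (the full table if larger).
#' @return data frame of the top \code{n} rows.
#' @export
rank_top_n <- function(fit, n = 50) {
  stopifnot(inherits(fit, "edge2_fit"))
  if (n < 1) pp_validation_error("'n' must be >= 1")
  s <- fit$scores
  ord <- order(-s$EDGE2_median, -s$ED2_median, s$taxon)
  head(s[ord, c("taxon", "category", "ED", "ED2_median",
                "EDGE2_median", "EDGE2_IQR", "rank")],
       min(n, nrow(s)))
}

#' EDGE2 score histogram bin counts
#'
#' Counts of taxa per fixed-width class of EDGE2 median (the tabular
#' equivalent of the score-distribution histogram).
#'
#' @param fit an \code{edge2_fit}.
#' @param width bin width in Myr (default 5).
#' @return data frame with \code{bin_low}, \code{bin_high}, \code{count};
#'   bins are \code{[low, high)}.
#' @export
edge2_bins <- function(fit, width = 5) {
  stopifnot(inherits(fit, "edge2_fit"))
  med <- fit$scores$EDGE2_median
  k <- floor(med / width)
  kmax <- max(k)
  cnt <- tabulate(k + 1L, nbins = kmax + 1L)
  data.frame(bin_low = width * (0:kmax),
             bin_high = width * (1:(kmax + 1)),
             count = cnt)
}

#' Write EDGE2 results as delimited tables
#'
#' @param fit an \code{edge2_fit}.
#' @param dir output directory (created if needed).
#' @param top_n rows in the ranking table.
#' @param bin_width histogram bin width (Myr).
#' @return named character vector of written paths, invisibly.
#' @export
write_edge2_results <- function(fit, dir, top_n = 50, bin_width = 5) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(scores = file.path(dir, "edge2_scores.csv"),
             top = file.path(dir, "edge2_top.csv"),
             bins = file.path(dir, "edge2_bins.csv"))
  write.csv(fit$scores, paths[["scores"]], row.names = FALSE, quote = FALSE)
  write.csv(rank_top_n(fit, top_n), paths[["top"]],
            row.names = FALSE, quote = FALSE)
  write.csv(edge2_bins(fit, bin_width), paths[["bins"]],
            row.names = FALSE, quote = FALSE)
  invisible(paths)
}
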