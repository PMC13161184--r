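# Red List tabulations and trait-threat rank correlations.
#
# Trait codings: habit (epiphyte/lithophyte = 1, terrestrial = 2), habitat
# specificity (generalist = 1, specialist = 2), mating system (selfing = 1,
# outcrossing = 2), trade (0 untraded, 1 ornamental, 2 medicinal, 3 both).
# Red List ordinals for correlation: LC = 1 .. CR = 5, RE = 6; DD/NE/NA are
# excluded pairwise.

#' Habitat specificity code from habitat-type membership
#'
#' Generalists (code 1) occur in two or more of the five habitat types;
#' specialists (code 2) are restricted to a single type.
#'
#' @param habitats a character vector of habitat-type names (one taxon), or
#'   a semicolon-joined string, or a list of such vectors (vectorized).
#' @return integer code(s) 1 (generalist) or 2 (specialist).
#' @export
#' @examples
#' classify_habitat_specificity("lowland_forest")                      # 2
#' classify_habitat_specificity("montane_forest;upland_grassland")     # 1
classify_habitat_specificity <- function(habitats) {
  if (is.list(habitats))
    return(vapply(habitats, classify_habitat_specificity, integer(1)))
  if (length(habitats) == 1L && grepl(";", habitats))
    habitats <- strsplit(habitats, ";", fixed = TRUE)[[1]]
  habitats <- unique(normalize_taxon(habitats[nzchar(trimws(habitats))]))
  if (!length(habitats))
    pp_validation_error("empty habitat membership")
  bad <- setdiff(habitats, HABITAT_TYPES)
  if (length(bad))
    pp_validation_error(sprintf("unknown habitat type(s): %s",
                                paste(bad, collapse = ", ")))
  if (length(habitats) >= 2L) 1L else 2L
}

#' Red List category tabulation for one scope
#'
#' Counts per category, the threatened tally (CR + EN + VU), and the
#' threatened percentage of assessed taxa.  Assessed excludes NE and NA but
#' includes DD and RE; percentages round half away from zero.
#'
#' @param table an \code{\link{assessment_table}}.
#' @param scope \code{"hk"} or \code{"cn"}.
#' @return list: \code{counts} (named, over the full vocabulary),
#'   \code{assessed}, \code{threatened}, \code{threatened_percent} (NA when
#'   nothing is assessed).
#' @export
tabulate_red_list <- function(table, scope = c("hk", "cn")) {
  scope <- match.arg(scope)
  cats <- scope_categories(table, scope, table$taxon)
  counts <- setNames(integer(length(RED_LIST_CATEGORIES)),
                     RED_LIST_CATEGORIES)
  tab <- table(cats)
  counts[names(tab)] <- as.integer(tab)
  assessed <- sum(counts[setdiff(RED_LIST_CATEGORIES, c("NE", "NA"))])
  threatened <- sum(counts[THREATENED_CATEGORIES])
  list(counts = counts,
       assessed = assessed,
       threatened = threatened,
       threatened_percent = if (assessed > 0)
         as.integer(round_half_up(100 * threatened / assessed)) else NA_integer_)
}

#' Trade tabulation
#'
#' Ornamental = codes 1 or 3, medicinal = codes 2 or 3, both = code 3;
#' traded total by inclusion-exclusion (equivalently: any non-zero code).
#'
#' @param table an \code{\link{assessment_table}} with a \code{trade}
#'   column.
#' @return list: \code{traded}, \code{ornamental}, \code{medicinal},
#'   \code{both}, \code{untraded}.
#' @export
tabulate_trade <- function(table) {
  if (!"trade" %in% names(table))
    pp_validation_error("no 'trade' column in table")
  v <- table$trade
  if (any(!v %in% 0:3))
    pp_validation_error("trade codes outside 0..3")
  ornamental <- sum(v %in% c(1L, 3L))
  medicinal <- sum(v %in% c(2L, 3L))
  both <- sum(v == 3L)
  list(traded = ornamental + medicinal - both,
       ornamental = ornamental, medicinal = medicinal, both = both,
       untraded = sum(v == 0L))
}

#' Threat rates per trait group
#'
#' For each level of a trait, the group size, the threatened count and
#' integer percentage, and the regionally-extinct count.
#'
#' @param table an \code{\link{assessment_table}}.
#' @param scope \code{"hk"} or \code{"cn"}.
#' @param trait one of \code{"habit"}, \code{"habitat_specificity"},
#'   \code{"mating"}, \code{"trade"}.
#' @return data frame: trait level, \code{n}, \code{threatened},
#'   \code{percent}, \code{re}.
#' @export
trait_group_threat_rates <- function(table, scope = c("hk", "cn"),
                                     trait = c("habitat_specificity", "habit",
                                               "mating", "trade")) {
  scope <- match.arg(scope)
  trait <- match.arg(trait)
  cats <- scope_categories(table, scope, table$taxon)
  tv <- trait_values(table, trait)
  keep <- !is.na(tv)
  levs <- sort(unique(tv[keep]))
  rows <- lapply(levs, function(l) {
    sel <- keep & tv == l
    n <- sum(sel)
    thr <- sum(cats[sel] %in% THREATENED_CATEGORIES)
    data.frame(level = l, n = n, threatened = thr,
               percent = as.integer(round_half_up(100 * thr / n)),
               re = sum(cats[sel] == "RE"))
  })
  out <- do.call(rbind, rows)
  out$trait <- trait
  out[, c("trait", "level", "n", "threatened", "percent", "re")]
}

# Extract a trait as an integer vector (NA = missing / not coded).
trait_values <- function(table, trait) {
  switch(trait,
    habitat_specificity = {
      if (!"habitats" %in% names(table))
        pp_validation_error("no 'habitats' column in table")
      sets <- parse_habitats(table$habitats)
      vapply(sets, function(h)
        if (!length(h)) NA_integer_ else classify_habitat_specificity(h),
        integer(1))
    },
    trade = {
      if (!"trade" %in% names(table))
        pp_validation_error("no 'trade' column in table")
      table$trade
    },
    {
      if (!trait %in% names(table))
        pp_validation_error(sprintf("no '%s' column in table", trait))
      table[[trait]]
    })
}

#' Tie-corrected Spearman rank correlation for ordinal data
#'
#' r_s is the Pearson correlation of mid-ranks.  The p-value uses the
#' t-approximation \code{t = r sqrt((n-2)/(1-r^2))} by default, or a seeded
#' permutation test (two-sided, on |r_s|).
#'
#' @param x,y numeric/ordinal vectors of equal length (pairs with NA in
#'   either are dropped); n >= 3 required after exclusion.
#' @param method \code{"t"} or \code{"permutation"}.
#' @param n_perm permutations when \code{method = "permutation"}.
#' @param seed optional RNG seed (permutation only).
#' @param trait optional trait name carried into the result.
#' @return list of class \code{spearman_cor}: \code{trait}, \code{n},
#'   \code{rho}, \code{p.value}, \code{method}, \code{strength}.
#' @export
#' @examples
#' spearman_correlation(1:10, (1:10)^2)$rho   # 1
spearman_correlation <- function(x, y, method = c("t", "permutation"),
                                 n_perm = 10000L, seed = NULL,
                                 trait = NA_character_) {
  method <- match.arg(method)
  keep <- complete.cases(x, y)
  x <- as.numeric(x[keep]); y <- as.numeric(y[keep])
  n <- length(x)
  if (n < 3L)
    pp_data_error(sprintf("need >= 3 complete pairs (have %d)", n))
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    pp_data_error("zero variance in one of the vectors: correlation undefined")
  r <- cor(x, y, method = "spearman")
  p <- if (method == "t") spearman_p_t(r, n)
  else {
    maybe_seed(seed)
    n_perm <- as.integer(n_perm)
    hits <- 0L
    ry <- rank(y)
    rx <- rank(x)
    for (b in seq_len(n_perm)) {
      rp <- cor(rx, ry[sample.int(n)])
      if (abs(rp) >= abs(r) - 1e-12) hits <- hits + 1L
    }
    (1 + hits) / (n_perm + 1)
  }
  structure(list(trait = trait, n = n, rho = r, p.value = p,
                 method = method,
                 strength = correlation_strength(r)),
            class = "spearman_cor")
}

spearman_p_t <- function(r, n) {
  if (abs(r) >= 1) return(0)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(tt), df = n - 2)
}

#' @rdname spearman_correlation
#' @param rho a correlation coefficient.
#' @export
correlation_strength <- function(rho) {
  a <- abs(rho)
  if (a < 0.2) "very weak"
  else if (a < 0.4) "weak"
  else if (a < 0.6) "moderate"
  else "strong"
}

#' @export
print.spearman_cor <- function(x, ...) {
  cat(sprintf("Spearman rank correlation%s: rho = %.3f (%s), p = %.3g (%s), n = %d\n",
              if (is.na(x$trait)) "" else sprintf(" [%s]", x$trait),
              x$rho, x$strength, x$p.value, x$method, x$n))
  invisible(x)
}

#' Trait-threat correlations across an assessment table
#'
#' Maps the scope's categories to ordinals (LC = 1 .. CR = 5, RE = 6,
#' DD/NE/NA excluded pairwise), extracts each requested trait, and runs
#' \code{\link{spearman_correlation}}.
#'
#' @param table an \code{\link{assessment_table}}.
#' @param scope \code{"hk"} or \code{"cn"}.
#' @param traits trait names (see \code{\link{trait_group_threat_rates}}).
#' @param ... passed to \code{\link{spearman_correlation}}.
#' @return data frame: trait, scope, n, rho, p.value, method, strength.
#' @export
trait_threat_correlations <- function(table, scope = c("hk", "cn"),
                                      traits = c("habit",
                                                 "habitat_specificity",
                                                 "mating", "trade"),
                                      ...) {
  scope <- match.arg(scope)
  cats <- scope_categories(table, scope, table$taxon)
  ord <- unname(THREAT_ORDINAL[cats])   # NA for EW/DD/NE/NA
  rows <- lapply(traits, function(tr) {
    tv <- trait_values(table, tr)
    res <- spearman_correlation(ord, tv, trait = tr, ...)
    data.frame(trait = tr, scope = scope, n = res$n, rho = res$rho,
               p.value = res$p.value, method = res$method,
               strength = res$strength, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
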