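# Per-category extinction-probability pools with pinned medians.
#
# Each ranked Red List category carries a stated 50-year extinction
# probability (the pool median) and a support interval.  A pool contains the
# median value itself plus equal numbers of uniform draws below and above it,
# so the empirical median equals the stated value exactly.  RE/EW taxa use
# the CR pool; DD/NE/NA taxa sample from the concatenation of all five pools.

GE2_MEDIANS <- c(CR = 0.97, EN = 0.485, VU = 0.2425,
                 NT = 0.12125, LC = 0.060625)

GE2_INTERVALS <- matrix(
  c(0.69436, 0.99999,   # CR
    0.33861, 0.69435,   # EN
    0.17085, 0.33861,   # VU
    0.09337, 0.17085,   # NT
    0.00174, 0.09337),  # LC
  ncol = 2, byrow = TRUE,
  dimnames = list(c("CR", "EN", "VU", "NT", "LC"), c("lower", "upper")))

#' Extinction-probability interval for a Red List category
#'
#' Returns the support interval of the 50-year extinction probability for a
#' category.  RE and EW share the CR interval; DD, NE and NA span the full
#' range (0.00174, 0.99999).
#'
#' @param category a single category token (see
#'   \code{\link{RED_LIST_CATEGORIES}}).
#' @return named numeric vector \code{c(lower, upper)}.
#' @export
#' @examples
#' category_interval("CR")
#' category_interval("DD")
category_interval <- function(category) {
  category <- normalize_categories(category)
  if (length(category) != 1L)
    pp_validation_error("'category' must be a single token")
  key <- switch(category,
                RE = , EW = "CR",
                DD = , NE = , "NA" = "ALL",
                category)
  if (key == "ALL")
    return(c(lower = min(GE2_INTERVALS[, "lower"]),
             upper = max(GE2_INTERVALS[, "upper"])))
  c(lower = GE2_INTERVALS[key, "lower"], upper = GE2_INTERVALS[key, "upper"])
}

#' Build a median-pinned extinction-probability pool for one category
#'
#' The pool holds the category's stated median once, plus
#' \code{(pool_size - 1) / 2} uniform draws on (lower, median) and the same
#' number on (median, upper); its empirical median therefore equals the
#' stated value exactly, and every value lies inside the category interval.
#'
#' @param category one of CR, EN, VU, NT, LC.
#' @param pool_size odd integer >= 3.
#' @param seed optional RNG seed for reproducibility.
#' @return numeric vector of length \code{pool_size}.
#' @export
build_risk_pool <- function(category, pool_size = 10001L, seed = NULL) {
  category <- normalize_categories(category)
  if (!category %in% rownames(GE2_INTERVALS))
    pp_validation_error(sprintf(
      "pools are defined for %s only (got '%s')",
      paste(rownames(GE2_INTERVALS), collapse = ", "), category))
  pool_size <- as.integer(pool_size)
  if (is.na(pool_size) || pool_size < 3L || pool_size %% 2L == 0L)
    pp_validation_error("'pool_size' must be an odd integer >= 3")
  maybe_seed(seed)
  m <- GE2_MEDIANS[[category]]
  lo <- GE2_INTERVALS[category, "lower"]
  hi <- GE2_INTERVALS[category, "upper"]
  half <- (pool_size - 1L) %/% 2L
  c(runif(half, lo, m), m, runif(half, m, hi))
}

#' Build the full extinction-risk model
#'
#' One median-pinned pool per ranked category plus their concatenation, from
#' which DD/NE/NA taxa are sampled.
#'
#' @param pool_size a single odd size used for all five categories, or a
#'   named vector with entries CR, EN, VU, NT, LC.
#' @param seed optional RNG seed.
#' @return an object of class \code{risk_model} with elements \code{pools}
#'   (named list), \code{pooled} (concatenation), \code{medians} and
#'   \code{intervals}.
#' @export
#' @examples
#' m <- build_risk_model(pool_size = 1001, seed = 1)
#' sapply(m$pools, median)
build_risk_model <- function(pool_size = 10001L, seed = NULL) {
  cats <- rownames(GE2_INTERVALS)
  sizes <- if (length(pool_size) == 1L)
    setNames(rep(as.integer(pool_size), length(cats)), cats)
  else {
    if (!all(cats %in% names(pool_size)))
      pp_validation_error("named 'pool_size' must cover CR, EN, VU, NT, LC")
    setNames(as.integer(pool_size[cats]), cats)
  }
  maybe_seed(seed)
  pools <- lapply(cats, function(cc) build_risk_pool(cc, sizes[[cc]]))
  names(pools) <- cats
  structure(list(pools = pools,
                 pooled = unlist(pools, use.names = FALSE),
                 medians = GE2_MEDIANS,
                 intervals = GE2_INTERVALS,
                 pool_size = sizes),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat("extinction-risk model (median-pinned pools)\n")
  med <- vapply(x$pools, median, numeric(1))
  tab <- data.frame(category = names(x$pools),
                    size = unname(x$pool_size[names(x$pools)]),
                    median = unname(med),
                    lower = x$intervals[names(x$pools), "lower"],
                    upper = x$intervals[names(x$pools), "upper"])
  print(tab, row.names = FALSE)
  cat(sprintf("pooled (DD/NE/NA) length: %d\n", length(x$pooled)))
  invisible(x)
}

#' Draw GE2 extinction probabilities for a taxon
#'
#' Samples with replacement from the pool matching the taxon's category:
#' ranked categories from their own pool, RE/EW from the CR pool, and
#' DD/NE/NA either from the pooled concatenation of all five pools (default)
#' or uniformly on the full interval.
#'
#' @param model a \code{\link{build_risk_model}} result.
#' @param category a category token.
#' @param n_draws number of draws (>= 1).
#' @param seed optional RNG seed.
#' @param dd_method for DD/NE/NA: \code{"pooled"} (empirical concatenation)
#'   or \code{"uniform"} (flat on the full range).
#' @return numeric vector of length \code{n_draws}, all in (0, 1).
#' @export
draw_ge2 <- function(model, category, n_draws = 500L, seed = NULL,
                     dd_method = c("pooled", "uniform")) {
  stopifnot(inherits(model, "risk_model"))
  dd_method <- match.arg(dd_method)
  category <- normalize_categories(category)
  n_draws <- as.integer(n_draws)
  if (is.na(n_draws) || n_draws < 1L)
    pp_validation_error("'n_draws' must be >= 1")
  maybe_seed(seed)
  draw_ge2_stream(model, category, n_draws, dd_method)
}

# Unseeded core used by both draw_ge2 and the edge2 pipeline; every call
# consumes exactly n_draws uniforms so that fixed-seed runs are comparable
# across category assignments.
draw_ge2_stream <- function(model, category, n_draws, dd_method) {
  key <- switch(category, RE = , EW = "CR",
                DD = , NE = , "NA" = "ALL", category)
  if (key == "ALL") {
    if (dd_method == "uniform") {
      iv <- category_interval("DD")
      return(runif(n_draws, iv[["lower"]], iv[["upper"]]))
    }
    pool <- model$pooled
  } else pool <- model$pools[[key]]
  pool[pmax(1L, ceiling(runif(n_draws) * length(pool)))]
}

#' Export / import a risk model as a delimited table
#'
#' Two-column CSV (category, value) allowing a run to be replayed
#' bit-exactly.
#'
#' @param model a \code{risk_model}.
#' @param path CSV path.
#' @return \code{write_risk_model}: the path invisibly;
#'   \code{read_risk_model}: a \code{risk_model}.
#' @export
write_risk_model <- function(model, path) {
  stopifnot(inherits(model, "risk_model"))
  df <- data.frame(
    category = rep(names(model$pools), lengths(model$pools)),
    value = unlist(model$pools, use.names = FALSE))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_risk_model
#' @export
read_risk_model <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("category", "value") %in% names(df)))
    pp_validation_error("risk-model table needs columns 'category' and 'value'")
  cats <- rownames(GE2_INTERVALS)
  pools <- lapply(cats, function(cc) df$value[df$category == cc])
  names(pools) <- cats
  for (cc in cats) {
    if (!length(pools[[cc]]))
      pp_validation_error(sprintf("no pool values for category %s", cc))
    if (median(pools[[cc]]) != GE2_MEDIANS[[cc]])
      pp_validation_error(sprintf(
        "pool median for %s is %.6g, expected %.6g",
        cc, median(pools[[cc]]), GE2_MEDIANS[[cc]]))
  }
  structure(list(pools = pools,
                 pooled = unlist(pools, use.names = FALSE),
                 medians = GE2_MEDIANS,
                 intervals = GE2_INTERVALS,
                 pool_size = lengths(pools)),
            class = "risk_model")
}
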