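# ED ~ extinction-risk-weight ordinary least squares.

#' Regression of evolutionary distinctiveness on threat weight
#'
#' Ordinary least squares of per-taxon ED (response) on the Red List weight
#' (LC = 0, NT = 1, VU = 2, EN = 3, CR = 4).  Taxa whose category in the
#' chosen scope is outside the weight map (RE, EW, DD, NE, NA) are excluded.
#' Both plain and adjusted r-squared are reported; the adjusted value can be
#' negative when the fit explains less than one predictor's worth of
#' variance.
#'
#' @param ed named numeric vector of per-tip ED scores
#'   (\code{\link{fair_proportion_ed}}).
#' @param assessments an \code{\link{assessment_table}} covering the names
#'   of \code{ed}.
#' @param scope \code{"hk"} or \code{"cn"}.
#' @param weights category-to-weight map (default the LC=0..CR=4 coding).
#' @return list of class \code{ed_threat_reg}: slope, intercept, r.squared,
#'   adj.r.squared, p.value (two-sided, on the slope), n, and the underlying
#'   \code{lm} fit.
#' @export
ed_threat_regression <- function(ed, assessments, scope = c("hk", "cn"),
                                 weights = THREAT_WEIGHTS) {
  scope <- match.arg(scope)
  cats <- scope_categories(assessments, scope, names(ed))
  keep <- cats %in% names(weights)
  if (sum(keep) < 3L)
    pp_data_error(sprintf(
      "need >= 3 taxa with categories in the weight map (have %d)", sum(keep)))
  w <- unname(weights[cats[keep]])
  y <- unname(ed[keep])
  if (length(unique(w)) < 2L)
    pp_data_error("zero variance in threat weights: degenerate predictor")
  if (length(unique(y)) < 2L)
    return(structure(list(slope = 0, intercept = y[1], r.squared = 0,
                          adj.r.squared = 0, p.value = NA_real_,
                          n = length(y), scope = scope, fit = NULL),
                     class = "ed_threat_reg"))
  fit <- lm(y ~ w)
  sm <- suppressWarnings(summary(fit))  # perfect fits are legitimate here
  p <- sm$coefficients["w", "Pr(>|t|)"]
  if (is.nan(p)) p <- NA_real_   # constant response: no test
  # constant response: slope 0, r2 defined as 0
  r2 <- if (is.nan(sm$r.squared)) 0 else sm$r.squared
  structure(list(slope = unname(coef(fit)[["w"]]),
                 intercept = unname(coef(fit)[[1]]),
                 r.squared = r2,
                 adj.r.squared = if (is.nan(sm$adj.r.squared)) 0
                                 else sm$adj.r.squared,
                 p.value = p,
                 n = length(y),
                 scope = scope,
                 fit = fit),
            class = "ed_threat_reg")
}

#' @export
print.ed_threat_reg <- function(x, ...) {
  cat(sprintf("ED ~ threat weight OLS (scope '%s', n = %d)\n", x$scope, x$n))
  cat(sprintf("  slope %.4g  intercept %.4g\n", x$slope, x$intercept))
  cat(sprintf("  r^2 %.4g  adjusted r^2 %.4g  p %.4g\n",
              x$r.squared, x$adj.r.squared, x$p.value))
  invisible(x)
}
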