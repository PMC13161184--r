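# Internal helpers shared across modules.

# Classed conditions so callers/tests can distinguish failure modes.
pp_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "phyloprior_error"),
                      call = call))
}

pp_validation_error <- function(msg) pp_stop(msg, "phyloprior_validation_error")
pp_format_error     <- function(msg) pp_stop(msg, "phyloprior_format_error")
pp_data_error       <- function(msg) pp_stop(msg, "phyloprior_data_error")

#' Canonicalize taxon labels
#'
#' Trims surrounding whitespace and collapses internal runs of spaces and/or
#' underscores to a single underscore, so that labels written by different
#' Newick/CSV writers compare equal.
#'
#' @param x character vector of taxon labels.
#' @return character vector of normalized labels.
#' @export
#' @examples
#' normalize_taxon(c("Vanilla  shenzhenica", "Vanilla_shenzhenica "))
normalize_taxon <- function(x) {
  x <- trimws(as.character(x))
  gsub("[ _]+", "_", x)
}

# Round half away from zero to integer (printed-percentage style; base round()
# rounds half to even).
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

# Evaluate expr under a private RNG stream seeded with `seed`, restoring the
# caller's stream afterwards. Used where internal randomization (e.g. the
# trait-calibration Monte Carlo) must not perturb user-visible draws.
with_private_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Set the RNG only when a seed is supplied; NULL leaves the current stream.
maybe_seed <- function(seed) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
      pp_validation_error("'seed' must be a single finite number")
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}
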