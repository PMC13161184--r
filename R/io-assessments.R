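# Assessment/trait table input.  One row per taxon; Red List categories at
# two scopes (regional and national) plus the four coded traits.

ASSESSMENT_COLUMNS <- c("taxon", "hk", "cn", "habit", "habitats",
                        "mating", "trade")

#' Construct an assessment table
#'
#' @param df data frame with columns \code{taxon}, one or both of the scope
#'   columns \code{hk} (regional) and \code{cn} (national), and optionally
#'   the trait columns \code{habit} (epiphyte/lithophyte = 1, terrestrial =
#'   2), \code{habitats} (semicolon-joined habitat-type names from
#'   \code{\link{HABITAT_TYPES}}), \code{mating} (selfing = 1, outcrossing =
#'   2) and \code{trade} (0 untraded, 1 ornamental, 2 medicinal, 3 both).
#' @return a validated data frame of class \code{assessment_table}.
#' @export
assessment_table <- function(df) {
  if (!"taxon" %in% names(df))
    pp_validation_error("assessment table needs a 'taxon' column")
  df$taxon <- normalize_taxon(df$taxon)
  if (any(!nzchar(df$taxon)))
    pp_validation_error("empty taxon label(s)")
  dup <- unique(df$taxon[duplicated(df$taxon)])
  if (length(dup))
    pp_validation_error(sprintf("duplicate taxon label(s): %s",
                                paste(dup, collapse = ", ")))
  scopes <- intersect(c("hk", "cn"), names(df))
  if (!length(scopes))
    pp_validation_error("need at least one scope column ('hk' or 'cn')")
  for (sc in scopes)
    df[[sc]] <- normalize_categories(df[[sc]], what = sprintf("'%s' category", sc))
  for (tr in c("habit", "mating")) {
    if (!tr %in% names(df)) next
    raw <- trimws(as.character(df[[tr]]))
    missing_tok <- is.na(raw) | raw == "" | toupper(raw) == "NA"
    v <- suppressWarnings(as.integer(df[[tr]]))
    bad <- which(!missing_tok & (is.na(v) | !v %in% c(1L, 2L)))
    if (length(bad))
      pp_validation_error(sprintf("'%s' codes must be 1, 2 or missing (rows %s)",
                                  tr, paste(bad, collapse = ", ")))
    v[!v %in% c(1L, 2L)] <- NA_integer_
    df[[tr]] <- v
  }
  if ("trade" %in% names(df)) {
    v <- df$trade
    v[is.na(v) | !nzchar(trimws(as.character(v))) |
        toupper(trimws(as.character(v))) == "NA"] <- 0L
    v2 <- suppressWarnings(as.integer(v))
    bad <- which(is.na(v2) | !v2 %in% 0:3)
    if (length(bad))
      pp_validation_error(sprintf("'trade' codes must be in 0..3 (rows %s)",
                                  paste(bad, collapse = ", ")))
    df$trade <- v2
  }
  if ("habitats" %in% names(df)) {
    df$habitats <- as.character(df$habitats)
    df$habitats[is.na(df$habitats)] <- ""
    sets <- parse_habitats(df$habitats)
    bad_types <- setdiff(unique(unlist(sets)), HABITAT_TYPES)
    if (length(bad_types))
      pp_validation_error(sprintf("unknown habitat type(s): %s (allowed: %s)",
                                  paste(bad_types, collapse = ", "),
                                  paste(HABITAT_TYPES, collapse = ", ")))
  }
  rownames(df) <- NULL
  class(df) <- c("assessment_table", "data.frame")
  df
}

parse_habitats <- function(x) {
  lapply(strsplit(as.character(x), ";", fixed = TRUE),
         function(h) unique(normalize_taxon(h[nzchar(trimws(h))])))
}

#' Read an assessment/trait table from CSV
#'
#' Comma-separated with a required header.  Unknown category tokens are
#' rejected with the offending rows named; blank category cells are stored as
#' the "NA" token.
#'
#' @param source path to a CSV file.
#' @return an \code{\link{assessment_table}}.
#' @export
read_assessments <- function(source) {
  df <- read.csv(source, stringsAsFactors = FALSE,
                 colClasses = "character", na.strings = character())
  assessment_table(df)
}

#' @rdname read_assessments
#' @param table an \code{assessment_table}.
#' @param path output CSV path.
#' @export
write_assessments <- function(table, path) {
  stopifnot(inherits(table, "assessment_table"))
  write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Categories for the given scope, aligned to `taxa`; errors name any taxa
# missing from the table.
scope_categories <- function(table, scope, taxa) {
  scope <- match.arg(scope, c("hk", "cn"))
  if (!scope %in% names(table))
    pp_validation_error(sprintf("scope column '%s' absent from table", scope))
  key <- normalize_taxon(table$taxon)
  idx <- match(normalize_taxon(taxa), key)
  if (anyNA(idx))
    pp_validation_error(sprintf("taxa absent from assessment table: %s",
                                paste(taxa[is.na(idx)], collapse = ", ")))
  setNames(table[[scope]][idx], taxa)
}
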