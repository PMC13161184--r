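# Red List vocabulary and codings used throughout.

#' Red List category vocabulary
#'
#' The closed set of category tokens accepted in assessment tables: the five
#' ranked IUCN categories (LC, NT, VU, EN, CR), regional/extinction statuses
#' (RE regionally extinct, EW extinct in the wild), and the unranked statuses
#' (DD data deficient, NE not evaluated, NA not available).  Blank cells in
#' input tables are stored as the "NA" token.
#'
#' @format character vector of category tokens.
#' @export
RED_LIST_CATEGORIES <- c("LC", "NT", "VU", "EN", "CR", "RE", "EW",
                         "DD", "NE", "NA")

#' @rdname RED_LIST_CATEGORIES
#' @export
THREATENED_CATEGORIES <- c("VU", "EN", "CR")

# Ordinal coding used for rank correlations (RE above CR; DD/NE/NA excluded).
THREAT_ORDINAL <- c(LC = 1, NT = 2, VU = 3, EN = 4, CR = 5, RE = 6)

# Weights used for the ED ~ extinction-risk regression.
THREAT_WEIGHTS <- c(LC = 0, NT = 1, VU = 2, EN = 3, CR = 4)

#' Recognized habitat types
#'
#' The five habitat types used for habitat-specificity coding: lowland and
#' hill forest, montane forest, upland grassland, shrubland, and upland
#' cliffs.
#'
#' @format character vector of habitat-type names.
#' @export
HABITAT_TYPES <- c("lowland_forest", "montane_forest", "upland_grassland",
                   "shrubland", "upland_cliff")

# Normalize a vector of category tokens: blanks/NA -> "NA", reject unknowns.
normalize_categories <- function(x, what = "category") {
  x <- trimws(toupper(as.character(x)))
  x[is.na(x) | x == ""] <- "NA"
  bad <- setdiff(unique(x), RED_LIST_CATEGORIES)
  if (length(bad))
    pp_validation_error(sprintf(
      "unknown %s token(s): %s (allowed: %s)", what,
      paste(bad, collapse = ", "),
      paste(RED_LIST_CATEGORIES, collapse = ", ")))
  x
}
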