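# Published summary inputs shipped with the package: the regional (Hong
# Kong) and national (China) Red List tallies for the 138 Hong Kong orchid
# taxa, and the four-marker genetic-diversity summary table.  These are
# printed aggregate values; the per-taxon expansion below is synthetic (it
# realizes the tallies and the published group margins deterministically,
# not the real species list).

#' Published Red List tallies
#'
#' Category counts per scope as published for the 138 Hong Kong orchid taxa:
#' 135 assessed regionally (CR 35, EN 17, VU 24, NT 8, LC 30, DD 4, RE 17)
#' and 130 nationally (CR 5, EN 16, VU 22, NT 13, LC 70, DD 4).
#'
#' @return data frame with columns scope, category, count.
#' @export
reference_tallies <- function() {
  read.csv(system.file("extdata", "redlist_tallies.csv",
                       package = "phyloprior"),
           stringsAsFactors = FALSE, colClasses = c("character", "character",
                                                    "integer"))
}

#' Published marker genetic-distance and diversity summary
#'
#' Per-marker (5.8S, matK, trnL-F, trnH-psbA) mean inter-/intra-specific
#' distances, diversity components, and the coefficient of differentiation,
#' as published.
#'
#' @return data frame, one row per marker.
#' @export
reference_marker_diversity <- function() {
  read.csv(system.file("extdata", "marker_diversity.csv",
                       package = "phyloprior"),
           stringsAsFactors = FALSE)
}

#' Synthetic per-taxon table realizing the published tallies
#'
#' Expands the published aggregate counts into a deterministic 138-row
#' assessment table whose margins reproduce the published figures: the
#' regional and national category tallies; 91 habitat specialists of whom 55
#' are threatened and 17 regionally extinct (generalists 47 / 21
#' threatened); 61 outcrossing taxa of whom 41 are threatened and 7
#' regionally extinct, 10 selfing of whom 5 are threatened (mating known for
#' 71 taxa); trade codes giving 48 ornamental, 9 medicinal, 7 both (50
#' traded); and 84 terrestrial vs 54 epiphytic/lithophytic taxa.  The
#' species identities are synthetic placeholders; only the margins are real.
#'
#' @return an \code{\link{assessment_table}} with 138 rows.
#' @export
#' @examples
#' tab <- reference_assessments()
#' tabulate_red_list(tab, "hk")$threatened   # 76
reference_assessments <- function() {
  n <- 138L
  taxon <- sprintf("taxon_%03d", seq_len(n))

  rep_counts <- function(tokens, counts, total) {
    v <- rep(tokens, counts)
    c(v, rep("NA", total - length(v)))
  }
  # regional: CR 1-35, EN 36-52, VU 53-76, NT 77-84, LC 85-114, DD 115-118,
  # RE 119-135, NA 136-138 (threatened = rows 1-76)
  hk <- rep_counts(c("CR", "EN", "VU", "NT", "LC", "DD", "RE"),
                   c(35L, 17L, 24L, 8L, 30L, 4L, 17L), n)
  cn <- rep_counts(c("CR", "EN", "VU", "NT", "LC", "DD"),
                   c(5L, 16L, 22L, 13L, 70L, 4L), n)

  # habitat specificity: specialists = 55 threatened (1-55) + all 17 RE
  # (119-135) + NT 77-84 + LC 85-95  -> 91; the rest are generalists (47,
  # of whom the remaining 21 threatened are VU 56-76)
  specialist <- logical(n)
  specialist[c(1:55, 119:135, 77:84, 85:95)] <- TRUE
  habitats <- ifelse(specialist, HABITAT_TYPES[1],
                     paste(HABITAT_TYPES[1], HABITAT_TYPES[2], sep = ";"))

  # mating: outcrossing 61 = 41 threatened (1-41) + 7 RE (119-125) + 13
  # others (85-97); selfing 10 = 5 threatened (42-46) + 5 others (98-102)
  mating <- rep(NA_integer_, n)
  mating[c(1:41, 119:125, 85:97)] <- 2L
  mating[c(42:46, 98:102)] <- 1L

  # trade: both = 1-7, ornamental-only = 8-48, medicinal-only = 49-50
  trade <- integer(n)
  trade[1:7] <- 3L
  trade[8:48] <- 1L
  trade[49:50] <- 2L

  # habit: terrestrial (2) for 84 taxa, epiphyte/lithophyte (1) for 54
  habit <- c(rep(2L, 84L), rep(1L, 54L))

  assessment_table(data.frame(
    taxon = taxon, hk = hk, cn = cn,
    habit = habit, habitats = habitats, mating = mating, trade = trade,
    stringsAsFactors = FALSE))
}
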