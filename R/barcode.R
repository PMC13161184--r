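# Barcode discriminatory power: Kimura two-parameter distances, the
# intra-/inter-specific partition, Nei-style diversity decomposition, and the
# barcoding-gap one-way ANOVA.

K2P_BASES <- c("A", "C", "G", "T")
K2P_PURINES <- c("A", "G")

#' Kimura two-parameter distance between two aligned sequences
#'
#' Sites where either sequence carries a gap or ambiguity code are excluded
#' (pairwise deletion).  With transition proportion P and transversion
#' proportion Q over the usable sites,
#' \code{d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)}.
#' When a log argument is non-positive the pair is saturated: \code{d} is
#' \code{NA} and the pair is flagged rather than clamped.
#'
#' @param seq1,seq2 character vectors of equal length (single bases).
#' @param min_sites minimum usable sites for the pair to be defined.
#' @return list: \code{usable}, \code{P}, \code{Q}, \code{d},
#'   \code{saturated}.
#' @export
#' @examples
#' k2p_distance(rep("A", 10), rep("A", 10))$d      # 0
#' k2p_distance(strsplit("ACGT", "")[[1]], strsplit("A-GT", "")[[1]])$usable
k2p_distance <- function(seq1, seq2, min_sites = 1L) {
  if (length(seq1) != length(seq2))
    pp_validation_error("sequences differ in aligned length")
  s1 <- toupper(seq1); s2 <- toupper(seq2)
  ok <- s1 %in% K2P_BASES & s2 %in% K2P_BASES
  usable <- sum(ok)
  if (usable == 0L)
    pp_data_error("no usable sites after pairwise deletion")
  s1 <- s1[ok]; s2 <- s2[ok]
  diff <- s1 != s2
  pur1 <- s1 %in% K2P_PURINES; pur2 <- s2 %in% K2P_PURINES
  ts <- sum(diff & (pur1 == pur2))   # A<->G, C<->T
  tv <- sum(diff & (pur1 != pur2))
  P <- ts / usable; Q <- tv / usable
  a1 <- 1 - 2 * P - Q; a2 <- 1 - 2 * Q
  saturated <- (a1 <= 0 || a2 <= 0)
  d <- if (saturated || usable < min_sites) NA_real_
       else -0.5 * log(a1) - 0.25 * log(a2)
  list(usable = usable, P = P, Q = Q, d = d,
       saturated = saturated, defined = !saturated && usable >= min_sites)
}

#' Pairwise K2P distances partitioned within and between species
#'
#' Computes all pairwise distances in an alignment and labels each defined
#' pair intraspecific (same species) or interspecific.  Intraspecific
#' statistics only arise for species represented by two or more accessions;
#' when there are none they are reported as absent (NA), not zero.
#'
#' @param aln a \code{\link{marker_alignment}} with at least 2 species.
#' @param min_sites minimum usable sites per pair (default 1; use ~50 for
#'   real markers).
#' @return object of class \code{marker_distances}: the pair table
#'   (\code{pairs}), \code{intra} and \code{inter} distance vectors,
#'   per-species within-species means (\code{within_species}), counts of
#'   undefined/saturated pairs, and the diversity summary (see
#'   \code{\link{diversity_decomposition}}).
#' @export
partition_distances <- function(aln, min_sites = 1L) {
  stopifnot(inherits(aln, "marker_alignment"))
  sp <- aln$species
  if (length(unique(sp)) < 2L)
    pp_validation_error("need >= 2 species for a partition")
  acc <- rownames(aln$seqs)
  pr <- combn(length(acc), 2)
  m <- ncol(pr)
  res <- data.frame(acc1 = acc[pr[1, ]], acc2 = acc[pr[2, ]],
                    species1 = unname(sp[pr[1, ]]),
                    species2 = unname(sp[pr[2, ]]),
                    usable = NA_integer_, P = NA_real_, Q = NA_real_,
                    d = NA_real_, same_species = NA, defined = FALSE,
                    stringsAsFactors = FALSE)
  for (k in seq_len(m)) {
    kd <- k2p_distance(aln$seqs[pr[1, k], ], aln$seqs[pr[2, k], ],
                       min_sites = min_sites)
    res$usable[k] <- kd$usable; res$P[k] <- kd$P; res$Q[k] <- kd$Q
    res$d[k] <- kd$d; res$defined[k] <- kd$defined
  }
  res$same_species <- res$species1 == res$species2
  def <- res[res$defined, , drop = FALSE]
  intra <- def$d[def$same_species]
  inter <- def$d[!def$same_species]
  within_species <- if (length(intra)) {
    tapply(def$d[def$same_species], def$species1[def$same_species], mean)
  } else NULL
  div <- if (nrow(def)) {
    pi_total <- mean(def$d)
    pi_within <- if (length(intra)) mean(within_species) else NA_real_
    if (is.na(pi_within) || pi_total <= 0) NULL
    else diversity_decomposition(pi_total, pi_within)
  } else NULL
  structure(list(marker = aln$marker,
                 pairs = res,
                 intra = intra, inter = inter,
                 within_species = within_species,
                 n_undefined = sum(!res$defined),
                 n_pairs = m,
                 intra_mean = if (length(intra)) mean(intra) else NA_real_,
                 inter_mean = if (length(inter)) mean(inter) else NA_real_,
                 overall_mean = if (nrow(def)) mean(def$d) else NA_real_,
                 diversity = div),
            class = "marker_distances")
}

#' @export
print.marker_distances <- function(x, ...) {
  cat(sprintf("K2P distances, marker '%s': %d pairs (%d defined)\n",
              x$marker, x$n_pairs, x$n_pairs - x$n_undefined))
  cat(sprintf("  intra: n=%d mean=%s   inter: n=%d mean=%s\n",
              length(x$intra),
              if (is.na(x$intra_mean)) "absent" else sprintf("%.4f", x$intra_mean),
              length(x$inter),
              if (is.na(x$inter_mean)) "absent" else sprintf("%.4f", x$inter_mean)))
  if (!is.null(x$diversity))
    cat(sprintf("  pi_total %.4f  pi_within %.4f  delta %.4f  coefficient %.4f\n",
                x$diversity$pi_total, x$diversity$pi_within,
                x$diversity$delta_between, x$diversity$coefficient))
  invisible(x)
}

#' Diversity decomposition within and between species
#'
#' Splits total mean diversity into its within-species component (the
#' equal-weight mean over species of within-species mean distance) and the
#' between-species remainder:
#' \code{delta_between = pi_total - pi_within}, and the coefficient of
#' differentiation \code{1 - pi_within / pi_total}, the fraction of total
#' diversity attributable to divergence between species.
#'
#' @param pi_total overall mean pairwise distance, or a
#'   \code{marker_distances} object.
#' @param pi_within equal-weight mean over species of the within-species
#'   mean distance (ignored when \code{pi_total} is a
#'   \code{marker_distances}).
#' @return list: \code{pi_total}, \code{pi_within}, \code{delta_between},
#'   \code{coefficient}.
#' @export
#' @examples
#' diversity_decomposition(0.0480, 0.0038)  # delta 0.0442
diversity_decomposition <- function(pi_total, pi_within = NULL) {
  if (inherits(pi_total, "marker_distances")) {
    md <- pi_total
    if (is.na(md$overall_mean) || is.null(md$within_species))
      pp_data_error("intra statistics absent; decomposition undefined")
    pi_within <- mean(md$within_species)
    pi_total <- md$overall_mean
  }
  if (!is.numeric(pi_total) || !is.numeric(pi_within))
    pp_validation_error("'pi_total' and 'pi_within' must be numeric")
  if (pi_total <= 0)
    pp_data_error("pi_total must be > 0 for the coefficient to be defined")
  list(pi_total = pi_total,
       pi_within = pi_within,
       delta_between = pi_total - pi_within,
       coefficient = 1 - pi_within / pi_total)
}

#' Barcoding-gap one-way ANOVA
#'
#' Fixed-effects one-way ANOVA treating each defined pairwise distance as an
#' observation in one of two groups (intraspecific vs interspecific).
#'
#' @param md a \code{\link{partition_distances}} result with both groups
#'   non-empty and total n >= 3.
#' @return list: \code{F}, \code{p.value}, \code{df}, group means and sizes.
#' @export
barcoding_gap_anova <- function(md) {
  stopifnot(inherits(md, "marker_distances"))
  if (!length(md$intra) || !length(md$inter))
    pp_data_error("both intraspecific and interspecific pairs are required")
  d <- c(md$intra, md$inter)
  if (length(d) < 3L)
    pp_data_error("need >= 3 distances in total")
  g <- factor(rep(c("intra", "inter"), c(length(md$intra), length(md$inter))))
  if (var(d) == 0) {
    # no variance at all: no gap to detect
    return(list(F = 0, p.value = 1, df = c(1L, length(d) - 2L),
                group_means = tapply(d, g, mean),
                group_n = tapply(d, g, length)))
  }
  av <- suppressWarnings(anova(lm(d ~ g)))
  Fv <- av$`F value`[1]
  p <- av$`Pr(>F)`[1]
  if (is.nan(Fv)) { Fv <- 0; p <- 1 }
  list(F = Fv, p.value = p, df = av$Df,
       group_means = tapply(d, g, mean),
       group_n = tapply(d, g, length))
}

#' Site-resampling bootstrap standard error of an alignment statistic
#'
#' Resamples aligned columns with replacement, recomputes the statistic on
#' each replicate alignment, and returns the standard deviation across
#' replicates.
#'
#' @param aln a \code{\link{marker_alignment}}.
#' @param statistic function taking a \code{marker_alignment} and returning
#'   a single number (may be NA when undefined on a replicate).
#' @param replicates number of bootstrap replicates (>= 2).
#' @param seed optional RNG seed.
#' @return the bootstrap standard error (one number).
#' @export
bootstrap_se <- function(aln, statistic, replicates = 500L, seed = NULL) {
  stopifnot(inherits(aln, "marker_alignment"))
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 2L)
    pp_validation_error("'replicates' must be >= 2")
  maybe_seed(seed)
  L <- ncol(aln$seqs)
  vals <- vapply(seq_len(replicates), function(r) {
    cols <- sample.int(L, L, replace = TRUE)
    boot <- aln
    boot$seqs <- aln$seqs[, cols, drop = FALSE]
    v <- tryCatch(statistic(boot), error = function(e) NA_real_)
    if (length(v) != 1L) NA_real_ else as.numeric(v)
  }, numeric(1))
  if (mean(is.na(vals)) > 0.5)
    pp_data_error("statistic undefined in more than half of the replicates")
  sd(vals, na.rm = TRUE)
}
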