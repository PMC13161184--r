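# Seeded generators for study-structured synthetic inputs: dated ultrametric
# trees, Red List categories, traits with a target rank association to
# threat, and multi-accession sequence sets with a barcoding gap.

#' Default category frequencies
#'
#' Regional frequencies follow the published tallies of 135 assessed taxa
#' (CR 35, EN 17, VU 24, NT 8, LC 30, DD 4, RE 17); national frequencies
#' follow the 130 assessed taxa (CR 5, EN 16, VU 22, NT 13, LC 70, DD 4).
#'
#' @name category_frequencies
#' @format named numeric vectors summing to 1.
#' @export
HK_CATEGORY_FREQUENCIES <- c(CR = 35, EN = 17, VU = 24, NT = 8,
                             LC = 30, DD = 4, RE = 17) / 135

#' @rdname category_frequencies
#' @export
CN_CATEGORY_FREQUENCIES <- c(CR = 5, EN = 16, VU = 22, NT = 13,
                             LC = 70, DD = 4) / 130

#' Simulate a dated ultrametric tree
#'
#' Pure-birth (Yule) tree with the requested number of extant tips, rescaled
#' so the root-to-tip depth equals \code{root_age} (all tips equidistant
#' from the root).
#'
#' @param n_taxa number of tips (>= 2).
#' @param birth birth rate (shape only; depths are rescaled).
#' @param root_age root age in Myr (default 110).
#' @param seed optional RNG seed.
#' @param labels optional tip labels (default \code{sp001, ...}).
#' @return a \code{phylo} object.
#' @export
#' @examples
#' tr <- simulate_tree(10, seed = 1)
#' max(ape::node.depth.edgelength(tr))  # 110
simulate_tree <- function(n_taxa, birth = 0.05, root_age = 110,
                          seed = NULL, labels = NULL) {
  n_taxa <- as.integer(n_taxa)
  if (is.na(n_taxa) || n_taxa < 2L)
    pp_validation_error("'n_taxa' must be >= 2")
  if (root_age <= 0) pp_validation_error("'root_age' must be > 0")
  maybe_seed(seed)
  tr <- ape::rphylo(n_taxa, birth = birth, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * root_age / depth
  tr$tip.label <- if (is.null(labels)) sprintf("sp%03d", seq_len(n_taxa))
                  else normalize_taxon(labels)
  validate_phylogeny(tr)
  tr
}

#' Simulate Red List categories
#'
#' Independent multinomial assignment with the given per-category
#' frequencies.
#'
#' @param tips character vector of taxon labels.
#' @param frequencies named frequencies over a subset of
#'   \code{\link{RED_LIST_CATEGORIES}}, summing to 1.
#' @param seed optional RNG seed.
#' @return named character vector of categories.
#' @export
simulate_categories <- function(tips, frequencies = HK_CATEGORY_FREQUENCIES,
                                seed = NULL) {
  if (is.null(names(frequencies)))
    pp_validation_error("'frequencies' must be named by category")
  cats <- normalize_categories(names(frequencies))
  if (abs(sum(frequencies) - 1) > 1e-8)
    pp_validation_error(sprintf("frequencies sum to %.6g, not 1",
                                sum(frequencies)))
  maybe_seed(seed)
  setNames(sample(cats, length(tips), replace = TRUE,
                  prob = frequencies),
           tips)
}

# ---- trait simulation: Gaussian-copula thresholding -----------------------

# Monte-Carlo calibration table latent-r -> Spearman, cached per marginal
# structure; computed under a private RNG stream so cache warmth never
# changes user-visible draws.
.calib_cache <- new.env(parent = emptyenv())

calibrate_latent_rho <- function(target, ord_freq, code_probs, codes,
                                 mc_n = 20000L) {
  key <- paste(signif(c(ord_freq, code_probs), 6), collapse = "|")
  tab <- .calib_cache[[key]]
  if (is.null(tab)) {
    tab <- with_private_seed(104729L, {
      grid <- c(0.15, 0.3, 0.45, 0.6, 0.75, 0.9, 0.99)
      ords <- sample(seq_along(ord_freq), mc_n, replace = TRUE,
                     prob = ord_freq)
      s <- ordinal_normal_scores(ords, length(ord_freq), ord_freq)
      eps <- rnorm(mc_n)
      cuts <- qnorm(cumsum(code_probs))
      rho_hat <- vapply(grid, function(rl) {
        z <- rl * s + sqrt(1 - rl^2) * eps
        tr <- codes[findInterval(z, cuts[-length(cuts)]) + 1L]
        cor(ords, tr, method = "spearman")
      }, numeric(1))
      # a latent correlation of zero maps to zero exactly, by symmetry
      list(grid = c(0, grid), rho = cummax(c(0, rho_hat)))
    })
    .calib_cache[[key]] <- tab
  }
  a <- abs(target)
  if (a > max(tab$rho) + 0.02)
    pp_stop(sprintf(
      "target Spearman %.3g unattainable for this trait (max ~ %.3g)",
      target, max(tab$rho)), "phyloprior_calibration_error")
  rl <- approx(tab$rho, tab$grid, xout = min(a, max(tab$rho)),
               ties = "ordered")$y
  sign(target) * rl
}

# Normal scores for ordinal levels: the expected standard-normal value of
# the mid-quantile of each level's band under the marginal frequencies.
ordinal_normal_scores <- function(ords, n_levels, freq) {
  cum <- c(0, cumsum(freq))
  mids <- qnorm(pmin(pmax((cum[-length(cum)] + cum[-1]) / 2, 1e-6), 1 - 1e-6))
  mids[ords]
}

#' Simulate a coded trait with a target rank association to threat
#'
#' Latent Gaussian threshold model: each taxon's latent value is correlated
#' (at a calibrated level) with the normal score of its threat ordinal, then
#' thresholded into the trait's code set at the requested prevalences.  The
#' latent correlation is calibrated by Monte Carlo so that the realized
#' Spearman correlation between threat ordinal and coded trait targets
#' \code{rho}.
#'
#' @param categories named character vector of Red List categories; taxa
#'   with categories outside the LC..RE ordinal map receive a trait drawn
#'   independently of threat.
#' @param rho target Spearman correlation in (-1, 1).
#' @param codes trait code values (default binary \code{c(1, 2)}).
#' @param prevalence prevalence of each code (sums to 1).
#' @param missing_fraction fraction of taxa set to NA (missing trait),
#'   chosen at random.
#' @param frequencies optional named category frequencies used to calibrate
#'   the latent correlation (the generating marginal law); defaults to the
#'   empirical frequencies of \code{categories}.  Supplying the generating
#'   frequencies keeps the calibration stable for small samples.
#' @param seed optional RNG seed.
#' @return named integer/numeric vector of trait codes (with NAs when
#'   \code{missing_fraction > 0}); attribute \code{"latent_rho"} records the
#'   calibrated latent correlation.
#' @export
simulate_traits <- function(categories, rho, codes = c(1L, 2L),
                            prevalence = c(0.5, 0.5),
                            missing_fraction = 0, frequencies = NULL,
                            seed = NULL) {
  if (abs(rho) >= 1) pp_validation_error("'rho' must lie in (-1, 1)")
  if (length(codes) != length(prevalence) ||
      abs(sum(prevalence) - 1) > 1e-8)
    pp_validation_error("'prevalence' must match 'codes' and sum to 1")
  cats <- normalize_categories(categories)
  ord <- THREAT_ORDINAL[cats]
  n <- length(cats)
  usable <- !is.na(ord)
  if (is.null(frequencies)) {
    freq <- tabulate(ord[usable], nbins = 6)
  } else {
    fcats <- normalize_categories(names(frequencies))
    ford <- THREAT_ORDINAL[fcats]
    freq <- numeric(6)
    freq[ford[!is.na(ford)]] <- frequencies[!is.na(ford)]
  }
  freq <- pmax(freq, 0) / sum(freq)
  rl <- calibrate_latent_rho(rho, freq, prevalence, codes)
  maybe_seed(seed)
  s <- numeric(n)
  s[usable] <- ordinal_normal_scores(ord[usable], 6, freq)
  s[!usable] <- 0                      # unranked taxa: no threat signal
  z <- rl * s + sqrt(1 - rl^2) * rnorm(n)
  cuts <- qnorm(cumsum(prevalence))
  out <- codes[findInterval(z, cuts[-length(cuts)]) + 1L]
  if (missing_fraction > 0)
    out[sample.int(n, round(missing_fraction * n))] <- NA
  names(out) <- names(categories)
  attr(out, "latent_rho") <- rl
  out
}

# ---- sequence simulation --------------------------------------------------

#' Simulate multi-accession marker sequences along a tree
#'
#' Evolves sequences under the Kimura two-parameter substitution process
#' (transition/transversion rate ratio \code{kappa}, equal base frequencies)
#' along the dated tree scaled to substitutions/site, then attaches
#' \code{accessions_per_species} accessions to every species as a star of
#' terminal branchlets of length \code{intra_divergence / 2}, so conspecific
#' accessions differ by \code{intra_divergence} expected substitutions/site.
#'
#' @param tree a dated \code{phylo} (branch lengths in Myr).
#' @param marker_length aligned sites.
#' @param kappa transition/transversion rate ratio (> 0).
#' @param inter_scale substitutions/site per Myr applied to the species tree.
#' @param intra_divergence expected intraspecific pairwise divergence
#'   (substitutions/site).
#' @param accessions_per_species accessions per species (>= 1).
#' @param seed optional RNG seed.
#' @param marker marker name.
#' @return a \code{\link{marker_alignment}}; accessions are labelled
#'   \code{<species>_1 ...}.
#' @export
simulate_sequences <- function(tree, marker_length = 800L, kappa = 3,
                               inter_scale = 4.5e-4,
                               intra_divergence = 0.003,
                               accessions_per_species = 3L,
                               seed = NULL, marker = "marker1") {
  validate_phylogeny(tree)
  if (kappa <= 0) pp_validation_error("'kappa' must be > 0")
  k <- as.integer(accessions_per_species)
  if (is.na(k) || k < 1L) pp_validation_error("'accessions_per_species' must be >= 1")
  maybe_seed(seed)
  sp_tree <- tree
  sp_tree$edge.length <- sp_tree$edge.length * inter_scale
  acc_tree <- attach_accessions(sp_tree, k, intra_divergence / 2)
  sim <- phangorn::simSeq(acc_tree, l = as.integer(marker_length),
                          Q = c(1, kappa, 1, 1, kappa, 1),
                          bf = rep(0.25, 4), type = "DNA")
  seqs <- toupper(as.character(sim))
  species <- setNames(sub("_[0-9]+$", "", rownames(seqs)), rownames(seqs))
  marker_alignment(seqs, species, marker = marker)
}

# Replace each tip of `tree` by a star of k accession branchlets of length
# `blen` (string-level rewrite of the Newick form).
attach_accessions <- function(tree, k, blen) {
  labs <- tree$tip.label
  if (k == 1L) {
    tree$tip.label <- paste0(labs, "_1")
    return(tree)
  }
  nwk <- ape::write.tree(tree)
  for (lab in labs) {
    inner <- paste(sprintf("%s_%d:%.10g", lab, seq_len(k), blen),
                   collapse = ",")
    nwk <- sub(paste0("([(,])", lab, ":"),
               paste0("\\1(", inner, "):"), nwk)
  }
  ape::read.tree(text = nwk)
}

#' Generate a complete, mutually consistent input bundle
#'
#' Produces (and optionally writes) a dated tree, an assessment/trait table
#' covering every tip at both scopes, and one multi-accession marker
#' alignment with its species map — the full input set for the scoring,
#' barcode and trait analyses.  Defaults emulate the study structure: 134
#' tips on a 110-Myr tree, regional and national category columns drawn at
#' the published frequencies, four traits with the published regional rank
#' associations (habitat 0.529, mating 0.369, trade 0.119, habit -0.041),
#' and a marker with intraspecific divergence two orders of magnitude below
#' interspecific divergence.
#'
#' @param dir output directory; \code{NULL} returns the bundle in memory
#'   only.
#' @param n_taxa number of species.
#' @param root_age root age (Myr).
#' @param hk_frequencies,cn_frequencies category frequencies per scope.
#' @param trait_rho named target Spearman correlations for the four traits.
#' @param marker_length,kappa,inter_scale,intra_divergence,accessions_per_species
#'   see \code{\link{simulate_sequences}}.
#' @param seed RNG seed (default 42); the whole bundle is a pure function of
#'   the configuration and seed.
#' @return list: \code{tree}, \code{assessments}, \code{alignment}, and
#'   \code{paths} (when written).
#' @export
make_fixture <- function(dir = NULL, n_taxa = 134L, root_age = 110,
                         hk_frequencies = HK_CATEGORY_FREQUENCIES,
                         cn_frequencies = CN_CATEGORY_FREQUENCIES,
                         trait_rho = c(habit = -0.041,
                                       habitat_specificity = 0.529,
                                       mating = 0.369, trade = 0.119),
                         marker_length = 800L, kappa = 3,
                         inter_scale = 4.5e-4, intra_divergence = 0.003,
                         accessions_per_species = 3L,
                         seed = 42L) {
  maybe_seed(seed)
  tree <- simulate_tree(n_taxa, root_age = root_age)
  tips <- tree$tip.label
  hk <- simulate_categories(tips, hk_frequencies)
  cn <- simulate_categories(tips, cn_frequencies)
  habit <- simulate_traits(hk, trait_rho[["habit"]], codes = c(1L, 2L),
                           prevalence = c(54, 84) / 138,
                           frequencies = hk_frequencies)
  hspec <- simulate_traits(hk, trait_rho[["habitat_specificity"]],
                           codes = c(1L, 2L), prevalence = c(47, 91) / 138,
                           frequencies = hk_frequencies)
  mating <- simulate_traits(hk, trait_rho[["mating"]], codes = c(1L, 2L),
                            prevalence = c(10, 61) / 71,
                            missing_fraction = 67 / 138,
                            frequencies = hk_frequencies)
  trade <- simulate_traits(hk, trait_rho[["trade"]], codes = 0:3,
                           prevalence = c(88, 41, 2, 7) / 138,
                           frequencies = hk_frequencies)
  habitats <- ifelse(hspec == 2L, HABITAT_TYPES[1],
                     paste(HABITAT_TYPES[1], HABITAT_TYPES[2], sep = ";"))
  tab <- assessment_table(data.frame(
    taxon = tips, hk = unname(hk), cn = unname(cn),
    habit = unname(habit), habitats = habitats,
    mating = unname(mating), trade = unname(trade),
    stringsAsFactors = FALSE))
  aln <- simulate_sequences(tree, marker_length = marker_length,
                            kappa = kappa, inter_scale = inter_scale,
                            intra_divergence = intra_divergence,
                            accessions_per_species = accessions_per_species)
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(tree = file.path(dir, "tree.nwk"),
               assessments = file.path(dir, "assessments.csv"),
               fasta = file.path(dir, "marker1.fasta"),
               species_map = file.path(dir, "species_map.csv"))
    write_newick(tree, paths[["tree"]])
    write_assessments(tab, paths[["assessments"]])
    write_fasta_alignment(aln, paths[["fasta"]], paths[["species_map"]])
  }
  list(tree = tree, assessments = tab, alignment = aln, paths = paths,
       seed = seed)
}
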