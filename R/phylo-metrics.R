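# Phylogenetic diversity, evolutionary distinctiveness, and ED2 (expected
# unique phylogenetic diversity under independent extinction of the other
# tips).  All metrics exclude any root edge.

# Precompute the incidence structures used by ED/ED2:
#   term_len  terminal branch length per tip (tree tip order)
#   M_desc    internal-edge x tip 0/1 matrix (tip descends from edge)
#   A_anc     tip x internal-edge 0/1 matrix (edge lies on tip's root path;
#             identical to t(M_desc), kept for readability)
#   int_len   internal edge lengths
tree_index <- function(tree) {
  validate_phylogeny(tree)
  n <- length(tree$tip.label)
  child <- tree$edge[, 2]
  terminal <- child <= n
  term_len <- numeric(n)
  term_len[child[terminal]] <- tree$edge.length[terminal]
  int_edges <- which(!terminal)
  M <- matrix(0, nrow = length(int_edges), ncol = n)
  if (length(int_edges)) {
    desc <- phangorn::Descendants(tree, child[int_edges], type = "tips")
    for (j in seq_along(int_edges)) M[j, desc[[j]]] <- 1
  }
  list(n_tip = n, tips = tree$tip.label,
       term_len = term_len,
       int_len = tree$edge.length[int_edges],
       M_desc = M,
       n_desc = rowSums(M))
}

#' Total phylogenetic diversity of a tree
#'
#' Sum of all non-root branch lengths (Myr on a dated tree).  A stored root
#' edge is excluded.
#'
#' @param tree a \code{phylo} object.
#' @return a single number.
#' @export
#' @examples
#' total_pd(read_newick("((A:1,B:1):1,C:2);"))  # 5
total_pd <- function(tree) {
  validate_phylogeny(tree)
  sum(tree$edge.length)
}

#' Evolutionary distinctiveness of every tip
#'
#' Fair proportion (default): each branch is shared equally among its
#' descendant tips, so per-tip scores sum exactly to the tree's PD.
#' Equal splits: a branch's length is halved at every split on the way down
#' to the tip (divided by the product of child counts below it).
#'
#' @param tree a \code{phylo} object.
#' @param method \code{"fair.proportion"} (default) or \code{"equal.splits"}.
#' @return named numeric vector of per-tip ED (Myr), in tree tip order.
#' @export
#' @examples
#' fair_proportion_ed(read_newick("((A:1,B:1):1,C:2);"))
fair_proportion_ed <- function(tree,
                               method = c("fair.proportion", "equal.splits")) {
  method <- match.arg(method)
  idx <- tree_index(tree)
  if (method == "fair.proportion") {
    ed <- idx$term_len
    if (length(idx$int_len))
      ed <- ed + as.vector(crossprod(idx$M_desc, idx$int_len / idx$n_desc))
    return(setNames(ed, idx$tips))
  }
  # equal splits: walk each tip's root path, halving at every split passed
  n <- idx$n_tip
  parent <- tree$edge[, 1]; child <- tree$edge[, 2]
  elen <- tree$edge.length
  nchildren <- tabulate(parent, nbins = max(parent))
  up <- setNames(parent, child)          # child node -> parent node
  upedge <- setNames(seq_along(child), child)
  ed <- numeric(n)
  root <- n + 1L
  for (i in seq_len(n)) {
    node <- i; share <- 1
    repeat {
      e <- upedge[[as.character(node)]]
      ed[i] <- ed[i] + elen[e] * share
      node <- up[[as.character(node)]]
      if (node == root) break
      share <- share / nchildren[node]
    }
  }
  setNames(ed, idx$tips)
}

#' ED2: expected unique phylogenetic diversity per tip
#'
#' For tip i, its terminal branch length plus each ancestral branch weighted
#' by the product of the extinction probabilities of that branch's other
#' descendant tips — the expected PD that would be lost with i if every other
#' tip k went extinct independently with probability \code{pext[k]}.  The
#' focal tip's own probability never enters its own score.
#'
#' @param tree a \code{phylo} object.
#' @param pext named numeric vector of extinction probabilities in (0, 1],
#'   covering every tip.
#' @return named numeric vector of per-tip ED2 (Myr), in tree tip order.
#' @export
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' ed2_scores(tr, c(A = 0.2, B = 0.5, C = 0.9))
ed2_scores <- function(tree, pext) {
  idx <- tree_index(tree)
  p <- align_pext(pext, idx$tips)
  out <- as.vector(ed2_from_index(idx, matrix(p, ncol = 1)))
  setNames(out, idx$tips)
}

align_pext <- function(pext, tips) {
  if (is.null(names(pext)))
    pp_validation_error("'pext' must be named by tip label")
  names(pext) <- normalize_taxon(names(pext))
  miss <- setdiff(tips, names(pext))
  if (length(miss))
    pp_validation_error(sprintf("tips missing from 'pext': %s",
                                paste(miss, collapse = ", ")))
  p <- pext[tips]
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    pp_validation_error("extinction probabilities must lie in (0, 1]")
  p
}

# Vectorized ED2 over draws: P is an n_tip x n_draw matrix of extinction
# probabilities; returns an n_tip x n_draw matrix of ED2 scores.  Products
# over descendant sets are taken in log space; the focal tip's factor is
# removed by dividing the edge product by its own probability.
ed2_from_index <- function(idx, P) {
  n_draw <- ncol(P)
  ED2 <- matrix(idx$term_len, nrow = idx$n_tip, ncol = n_draw)
  if (length(idx$int_len)) {
    S <- idx$M_desc %*% log(P)                 # edge x draw: sum log p
    W <- idx$int_len * exp(S)                  # edge x draw: L * prod p
    ED2 <- ED2 + crossprod(idx$M_desc, W) / P  # remove own factor
  }
  ED2
}
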