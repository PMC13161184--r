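# Newick tree input/output (backed by ape), with validation of the
# invariants the downstream metrics rely on.

#' Read and validate a rooted, dated Newick tree
#'
#' Parses a Newick string or file into an \code{ape::phylo} object and checks
#' the invariants assumed by the phylogenetic metrics: at least two tips,
#' unique non-empty tip labels, and finite non-negative branch lengths on
#' every non-root edge.  Quoted labels and scientific-notation lengths are
#' accepted.  A root edge length, if present, is retained on the object but
#' excluded from all metrics (PD, ED, ED2 operate on the ingroup tree).
#'
#' @param source path to a Newick file, or a Newick string (recognized by the
#'   presence of a parenthesized, semicolon-terminated topology).
#' @return a validated \code{phylo} object; tip labels are normalized with
#'   \code{\link{normalize_taxon}}.
#' @seealso \code{\link{write_newick}}
#' @export
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' total_pd(tr)
read_newick <- function(source) {
  if (length(source) != 1L || !is.character(source))
    pp_validation_error("'source' must be a single path or Newick string")
  txt <- if (grepl("\\(", source)) source
         else paste(readLines(source, warn = FALSE), collapse = "")
  check_newick_syntax(txt)
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr))
    pp_format_error("Newick parse failure (unrecognized structure)")
  if (inherits(tr, "multiPhylo"))
    pp_format_error("input contains more than one tree; a single root is required")
  tr$tip.label <- normalize_taxon(gsub("^'(.*)'$", "\\1", tr$tip.label))
  validate_phylogeny(tr)
  tr
}

# Cheap pre-scan so parse failures can name a character offset.
check_newick_syntax <- function(txt) {
  chars <- strsplit(txt, "")[[1]]
  depth <- 0L
  in_quote <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") in_quote <- !in_quote
    if (in_quote) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        pp_format_error(sprintf(
          "Newick parse failure: unbalanced ')' at character %d", i))
    }
  }
  if (in_quote)
    pp_format_error("Newick parse failure: unterminated quoted label")
  if (depth != 0L)
    pp_format_error(sprintf(
      "Newick parse failure: %d unclosed '(' by character %d", depth,
      nchar(txt)))
  if (!grepl(";", txt))
    pp_format_error(sprintf(
      "Newick parse failure: missing ';' terminator at character %d",
      nchar(txt)))
  invisible(TRUE)
}

#' Validate phylogeny invariants
#'
#' @param tree a \code{phylo} object.
#' @return the tree, invisibly, if valid; otherwise a validation error.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo"))
    pp_validation_error("not a 'phylo' object")
  n <- length(tree$tip.label)
  if (n < 2L)
    pp_validation_error("tree has fewer than 2 tips")
  labs <- tree$tip.label
  if (any(!nzchar(labs)))
    pp_validation_error("empty tip label(s)")
  dup <- unique(labs[duplicated(labs)])
  if (length(dup))
    pp_validation_error(sprintf("duplicate tip label(s): %s",
                                paste(dup, collapse = ", ")))
  if (is.null(tree$edge.length))
    pp_validation_error("tree has no branch lengths")
  el <- tree$edge.length
  if (any(!is.finite(el)) || any(el < 0))
    pp_validation_error("branch lengths must be finite and >= 0")
  invisible(tree)
}

#' Write a tree as Newick
#'
#' @param tree a \code{phylo} object.
#' @param path output file; if \code{NULL}, the Newick string is returned.
#' @return the path (invisibly) or the Newick string.
#' @export
write_newick <- function(tree, path = NULL) {
  validate_phylogeny(tree)
  if (is.null(path)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = path)
  invisible(path)
}
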