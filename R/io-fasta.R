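# FASTA alignment input and the marker_alignment container.

#' Construct a marker alignment
#'
#' A marker alignment holds equal-length aligned sequences (uppercase
#' character matrix, one row per accession) together with an
#' accession-to-species map.
#'
#' @param seqs character matrix (rows = accessions, columns = aligned sites)
#'   or a list of equal-length character vectors named by accession.
#' @param species named character vector mapping accession -> species label;
#'   must cover every accession.
#' @param marker marker name (informational).
#' @return an object of class \code{marker_alignment}.
#' @export
marker_alignment <- function(seqs, species, marker = "marker") {
  if (is.list(seqs)) {
    lens <- lengths(seqs)
    if (length(unique(lens)) > 1L)
      pp_format_error(sprintf(
        "ragged alignment: sequence lengths %s",
        paste(sort(unique(lens)), collapse = ", ")))
    seqs <- do.call(rbind, seqs)
  }
  if (!is.matrix(seqs) || !is.character(seqs))
    pp_validation_error("'seqs' must be a character matrix or list of character vectors")
  seqs[] <- toupper(seqs)
  acc <- rownames(seqs)
  if (is.null(acc) || any(!nzchar(acc)))
    pp_validation_error("every accession needs a non-empty name")
  if (anyDuplicated(acc))
    pp_validation_error("duplicate accession names")
  species <- vapply(species, as.character, character(1))
  unmapped <- setdiff(acc, names(species))
  if (length(unmapped))
    pp_validation_error(sprintf("accession(s) not in species map: %s",
                                paste(unmapped, collapse = ", ")))
  structure(list(seqs = seqs,
                 species = species[acc],
                 marker = marker),
            class = "marker_alignment")
}

#' Read a FASTA alignment with an accession-to-species map
#'
#' Sequences are case-folded to upper; all records must have equal aligned
#' length, and every accession must appear in the map.
#'
#' @param source path to a FASTA file.
#' @param species_map a data frame with columns \code{accession} and
#'   \code{species}, or a path to a CSV with those columns.
#' @param marker marker name stored on the result.
#' @return a \code{\link{marker_alignment}}.
#' @export
read_fasta_alignment <- function(source, species_map, marker = "marker") {
  dna <- ape::read.FASTA(source)
  if (length(dna) == 0L) pp_format_error("no FASTA records found")
  seqs <- lapply(as.character(dna), function(s) toupper(s))
  if (is.character(species_map) && length(species_map) == 1L)
    species_map <- read.csv(species_map, stringsAsFactors = FALSE)
  if (!all(c("accession", "species") %in% names(species_map)))
    pp_validation_error("species map needs columns 'accession' and 'species'")
  sp <- setNames(as.character(species_map$species),
                 as.character(species_map$accession))
  marker_alignment(seqs, sp, marker = marker)
}

#' Write a marker alignment as FASTA (plus optional species-map CSV)
#'
#' @param aln a \code{marker_alignment}.
#' @param path FASTA output path.
#' @param map_path optional CSV path for the accession/species map.
#' @return \code{path}, invisibly.
#' @export
write_fasta_alignment <- function(aln, path, map_path = NULL) {
  stopifnot(inherits(aln, "marker_alignment"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(aln$seqs))) {
    writeLines(paste0(">", rownames(aln$seqs)[i]), con)
    writeLines(paste(aln$seqs[i, ], collapse = ""), con)
  }
  if (!is.null(map_path))
    write.csv(data.frame(accession = names(aln$species),
                         species = unname(aln$species)),
              map_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.marker_alignment <- function(x, ...) {
  cat(sprintf("marker alignment '%s': %d accessions x %d sites, %d species\n",
              x$marker, nrow(x$seqs), ncol(x$seqs),
              length(unique(x$species))))
  invisible(x)
}
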