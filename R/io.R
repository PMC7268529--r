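## Standard-format I/O: FASTA via Biostrings, TSV with fixed conventions,
## Newick via ape. All writers are byte-deterministic given equal inputs.

#' Read unigene sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @param species optional species tag; if `NULL`, parsed from the header
#'   prefix before the first underscore (e.g. `T1_gene0001` -> `T1`).
#' @return Data frame with columns `id`, `species`, `seq`.
#' @export
read_fasta <- function(path, species = NULL) {
  set <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) stop("duplicate FASTA ids in ", path)
  sp <- if (is.null(species)) sub("_.*$", "", ids) else rep(species, length(ids))
  data.frame(id = ids, species = sp, seq = as.character(set),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of nucleotide sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

## TSV conventions: tab-separated, header, no quoting or row names
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Read a gene-to-term annotation table
#'
#' @param path TSV with columns `gene_id`, `term_id` and optionally
#'   `ontology`.
#' @return Data frame.
#' @export
read_annotation <- function(path) {
  ann <- read_tsv(path)
  if (!all(c("gene_id", "term_id") %in% names(ann)))
    stop("annotation file needs columns gene_id, term_id")
  ann
}

#' Write a phylogenetic tree in Newick format
#'
#' Bootstrap supports stored in `node.label` are written as internal node
#' labels.
#'
#' @param tree an `ape::phylo` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
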