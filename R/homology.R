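## Cross-species protein homology graph, Markov clustering into gene
## families, and copy-class / Venn accounting.

.KA_PROTEIN <- c(lambda = 0.267, K = 0.041)   # gapped BLOSUM62, open 11 ext 1
.KA_NT <- c(lambda = 0.625, K = 0.410)        # match 2 / mismatch -3, gap 5/2

## cached copy of the BLOSUM62 matrix shipped with Biostrings
blosum62_matrix <- function() {
  if (is.null(.ploidtrace_cache$blosum62)) {
    e <- new.env()
    data("BLOSUM62", package = "Biostrings", envir = e)
    .ploidtrace_cache$blosum62 <- e$BLOSUM62
  }
  .ploidtrace_cache$blosum62
}

#' Local protein alignment similarity edge
#'
#' Smith-Waterman local alignment (BLOSUM62, affine gaps: open 11, extend 1)
#' between two proteins, summarized as a similarity edge. The e-value proxy
#' is a Karlin-Altschul style quantity `K m n exp(-lambda S)` with fixed
#' gapped parameters and the product of the two sequence lengths as the
#' effective search space; it gates edges at `evalue_max`.
#'
#' @param prot_a,prot_b amino-acid strings.
#' @param evalue_max threshold above which no edge is returned
#'   (default `1e-7`, the nominal homology cutoff).
#' @return A one-row data frame (`gene_a`, `gene_b`, `score`, `identity`,
#'   `aligned_len`, `evalue_proxy`) in canonical `gene_a < gene_b` order,
#'   or `NULL` if the pair does not pass the threshold.
#' @export
pairwise_similarity <- function(prot_a, prot_b, evalue_max = 1e-7) {
  ids <- c(if (!is.null(names(prot_a))) names(prot_a) else "seq_a",
           if (!is.null(names(prot_b))) names(prot_b) else "seq_b")
  a <- toupper(prot_a[[1]]); b <- toupper(prot_b[[1]])
  if (!nzchar(a) || !nzchar(b)) stop("empty protein sequence")
  BLOSUM62 <- blosum62_matrix()
  ok <- paste(rownames(BLOSUM62), collapse = "")
  for (s in c(a, b)) {
    bad <- regexpr(sprintf("[^%s]", ok), s)
    if (bad > 0)
      stop("invalid amino-acid character '", substr(s, bad, bad),
           "' at position ", bad)
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = BLOSUM62, gapOpening = 11, gapExtension = 1)
  edge_from_alignment(ids, a, b, aln, .KA_PROTEIN, evalue_max)
}

edge_from_alignment <- function(ids, a, b, aln, ka, evalue_max) {
  score <- Biostrings::score(aln)
  alen <- nchar(as.character(Biostrings::alignedPattern(aln)))
  ident <- Biostrings::nmatch(aln) / alen
  ev <- ka[["K"]] * nchar(a) * nchar(b) * exp(-ka[["lambda"]] * score)
  if (ev > evalue_max) return(NULL)
  o <- order(ids)
  data.frame(gene_a = ids[o[1]], gene_b = ids[o[2]], score = score,
             identity = ident, aligned_len = alen, evalue_proxy = ev,
             stringsAsFactors = FALSE)
}

## shared-k-mer candidate prefilter: pairs of sequences sharing >= min_shared
## distinct k-mers. `groups`, if given, restricts to pairs within the same
## group (intra-species) or across groups (inter allowed when NULL).
kmer_candidate_pairs <- function(seqs, k, min_shared = 2L) {
  ids <- names(seqs)
  km <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, 1:(n - k + 1L), k:n))
  })
  idx <- rep(seq_along(ids), lengths(km))
  tab <- split(idx, unlist(km, use.names = FALSE))
  counts <- new.env(parent = emptyenv(), hash = TRUE)
  for (g in tab) {
    g <- unique(g)
    if (length(g) < 2L || length(g) > 100L) next
    for (pair in combn(sort(g), 2L, simplify = FALSE)) {
      key <- paste(pair, collapse = ":")
      counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
    }
  }
  keys <- ls(counts)
  if (!length(keys)) return(matrix(integer(0), ncol = 2))
  n_shared <- vapply(keys, function(k2) counts[[k2]], 0L)
  keep <- keys[n_shared >= min_shared]
  out <- do.call(rbind, lapply(strsplit(keep, ":"), as.integer))
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

#' All-vs-all protein homology edges
#'
#' Candidate pairs are prefiltered by shared 4-mers (>= 2), then scored with
#' [pairwise_similarity()]. Pairs from the same species are included
#' (paralog edges are what lets multi-copy families cluster together).
#'
#' @param proteins named character vector of protein sequences.
#' @param evalue_max homology e-value threshold (default `1e-7`).
#' @return Data frame of similarity edges in canonical order.
#' @export
homology_edges <- function(proteins, evalue_max = 1e-7) {
  stopifnot(!is.null(names(proteins)))
  cand <- kmer_candidate_pairs(proteins, k = 4L, min_shared = 2L)
  rows <- vector("list", nrow(cand))
  ids <- names(proteins)
  for (i in seq_len(nrow(cand))) {
    ia <- cand[i, 1]; ib <- cand[i, 2]
    e <- pairwise_similarity(setNames(proteins[ia], ids[ia]),
                             setNames(proteins[ib], ids[ib]),
                             evalue_max = evalue_max)
    rows[[i]] <- e
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      score = numeric(0), identity = numeric(0),
                      aligned_len = integer(0), evalue_proxy = numeric(0)))
  out <- do.call(rbind, rows)
  out[order(out$gene_a, out$gene_b), , drop = FALSE]
}

#' Markov clustering of a weighted similarity graph
#'
#' Column-normalizes the score-weighted adjacency matrix (self-loops set to
#' each column's maximum weight), then iterates expansion (matrix square)
#' and inflation (elementwise power + renormalization) until the matrix
#' changes by less than `tol` or `max_iter` iterations. Clusters are the
#' connected components of the limit matrix's support; genes with no edges
#' become singletons.
#'
#' @param edges data frame with `gene_a`, `gene_b`, `score` (canonical
#'   order).
#' @param inflation inflation exponent, > 1 (default 2).
#' @param genes optional character vector of all genes (so isolated genes
#'   are returned as singleton clusters).
#' @param tol,max_iter convergence controls.
#' @return List of character vectors, each a cluster; sorted by first
#'   member for determinism.
#' @export
mcl_cluster <- function(edges, inflation = 2, genes = NULL, tol = 1e-6,
                        max_iter = 200L) {
  if (inflation <= 1) stop("inflation must be > 1")
  universe <- sort(unique(c(edges$gene_a, edges$gene_b, genes)))
  if (!length(universe)) return(list())
  ## flow between graph components is identically zero, so MCL decomposes
  ## over connected components; iterate only within each component
  g0 <- igraph::graph_from_data_frame(
    edges[, c("gene_a", "gene_b")], directed = FALSE,
    vertices = data.frame(name = universe))
  comp0 <- igraph::components(g0)$membership[universe]
  out <- list()
  for (members in split(universe, comp0)) {
    if (length(members) <= 2L) {
      out[[length(out) + 1L]] <- sort(members)
      next
    }
    sub <- edges[edges$gene_a %in% members & edges$gene_b %in% members, ,
                 drop = FALSE]
    for (cl in mcl_component(sub, members, inflation, tol, max_iter))
      out[[length(out) + 1L]] <- cl
  }
  out[order(vapply(out, `[[`, "", 1L))]
}

mcl_component <- function(edges, members, inflation, tol, max_iter) {
  members <- sort(members)
  n <- length(members)
  M <- matrix(0, n, n, dimnames = list(members, members))
  ia <- match(edges$gene_a, members)
  ib <- match(edges$gene_b, members)
  M[cbind(ia, ib)] <- edges$score
  M[cbind(ib, ia)] <- edges$score
  loop <- apply(M, 2, max)
  loop[loop == 0] <- 1
  diag(M) <- loop
  normalize <- function(m) sweep(m, 2, colSums(m), "/")
  M <- normalize(M)
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M                    # expansion
    M2 <- M2 ^ inflation             # inflation
    M2[M2 < 1e-12] <- 0
    M2 <- normalize(M2)
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) break
  }
  g <- igraph::graph_from_adjacency_matrix(M > 0, mode = "max", diag = FALSE)
  comp <- igraph::components(g)$membership
  lapply(split(members, comp), sort)
}

#' Classify gene families into copy classes with Venn accounting
#'
#' A family is `shared_single_copy` iff it has exactly one gene from each of
#' the three species; `shared_multi_copy` iff all three species are present
#' and at least one contributes two or more genes; `partial_shared` iff
#' exactly two species are present; `species_specific` iff one.
#'
#' @param families list of character vectors of gene ids (clusters).
#' @param species_of named character vector mapping gene id to species tag.
#' @param species_levels the full species set (default `T1`,`T2`,`T3`).
#' @return A `gene_families` object: data frame (`family_id`, `gene_id`,
#'   `species`, `copy_class`) with attribute `venn`, a data frame of
#'   family and gene counts per region of the 3-set Venn diagram.
#' @export
classify_families <- function(families, species_of,
                              species_levels = c("T1", "T2", "T3")) {
  rows <- vector("list", length(families))
  regions <- character(length(families))
  classes <- character(length(families))
  for (i in seq_along(families)) {
    members <- families[[i]]
    sp <- species_of[members]
    if (anyNA(sp)) stop("unknown gene id: ", members[is.na(sp)][1])
    present <- sort(unique(sp))
    counts <- table(factor(sp, levels = species_levels))
    cls <- if (length(present) == 1L) "species_specific"
    else if (length(present) == 2L) "partial_shared"
    else if (max(counts) == 1L) "shared_single_copy"
    else "shared_multi_copy"
    classes[i] <- cls
    regions[i] <- paste(present, collapse = "&")
    rows[[i]] <- data.frame(
      family_id = sprintf("F%05d", i), gene_id = members,
      species = unname(sp), copy_class = cls, stringsAsFactors = FALSE)
  }
  all_regions <- unlist(lapply(1:3, function(k)
    combn(species_levels, k, paste, collapse = "&")))
  venn <- data.frame(
    region = all_regions,
    n_families = vapply(all_regions, function(r) sum(regions == r), 0L),
    n_genes = vapply(all_regions, function(r)
      sum(lengths(families)[regions == r]), 0L),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(do.call(rbind, rows), venn = venn,
            class = c("gene_families", "data.frame"))
}

#' Venn region counts of a `gene_families` object
#' @param families a `gene_families` object.
#' @return Data frame of family and gene counts per Venn region.
#' @export
venn_counts <- function(families) attr(families, "venn")

#' @export
print.gene_families <- function(x, ...) {
  cat(sprintf("gene_families: %d genes in %d families\n",
              nrow(x), length(unique(x$family_id))))
  print(table(x$copy_class[!duplicated(x$family_id)]))
  invisible(x)
}
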