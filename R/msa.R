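## Progressive multiple alignment: k-mer guide distances, average-linkage
## guide tree, profile-profile merges via an affine-gap (Gotoh) DP.

msa_alphabet <- function(type) {
  if (type == "dna") .BASES else setdiff(rownames(blosum62_matrix()), "*")
}

msa_submat <- function(type) {
  if (type == "dna") {
    m <- matrix(-3, 4, 4, dimnames = list(.BASES, .BASES))
    diag(m) <- 2
    m
  } else {
    alpha <- msa_alphabet("protein")
    blosum62_matrix()[alpha, alpha]
  }
}

## fraction-of-shared-k-mers distance used only for the guide tree
kmer_guide_dist <- function(seqs, k) {
  km <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, 1:(n - k + 1L), k:n))
  })
  n <- length(seqs)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      denom <- min(length(km[[i]]), length(km[[j]]))
      shared <- if (denom == 0) 0 else length(intersect(km[[i]], km[[j]]))
      d[i, j] <- d[j, i] <- 1 - if (denom == 0) 0 else shared / denom
    }
  }
  d
}

## character matrix (rows = sequences) -> residue frequency profile
seq_profile <- function(mat, alpha) {
  apply(mat, 2, function(col) {
    tabulate(factor(col, levels = alpha), nbins = length(alpha))
  }) / nrow(mat)
}

merge_profiles <- function(m1, m2, submat, alpha, gap_open, gap_ext) {
  p1 <- seq_profile(m1, alpha)
  p2 <- seq_profile(m2, alpha)
  if (!is.matrix(p1)) p1 <- matrix(p1, ncol = ncol(m1))
  if (!is.matrix(p2)) p2 <- matrix(p2, ncol = ncol(m2))
  cs <- crossprod(p1, submat %*% p2)   # expected column substitution scores
  ops <- profile_align_dp(cs, gap_open, gap_ext)
  L <- length(ops)
  out <- matrix("-", nrow(m1) + nrow(m2), L,
                dimnames = list(c(rownames(m1), rownames(m2)), NULL))
  i <- 0L; j <- 0L
  for (k in seq_len(L)) {
    op <- ops[k]
    if (op != 3L) { i <- i + 1L; out[seq_len(nrow(m1)), k] <- m1[, i] }
    if (op != 2L) { j <- j + 1L; out[nrow(m1) + seq_len(nrow(m2)), k] <- m2[, j] }
  }
  out
}

#' Progressive multiple sequence alignment
#'
#' Deterministic guide-tree progressive alignment: pairwise k-mer distances
#' feed an average-linkage guide tree, and groups are merged by
#' profile-profile global alignment with affine gap penalties (Gotoh DP).
#' DNA uses match 2 / mismatch -3 with gap open 5, extend 2; proteins use
#' BLOSUM62 with gap open 11, extend 1.
#'
#' @param seqs named character vector of >= 1 sequences (no gaps).
#' @param type `"dna"` or `"protein"`.
#' @return Character matrix of aligned sequences (rows = input sequences,
#'   gaps as `-`), rows in input order.
#' @export
progressive_align <- function(seqs, type = c("dna", "protein")) {
  type <- match.arg(type)
  if (length(seqs) < 1L) stop("progressive_align needs at least one sequence")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  seqs <- vapply(seqs, toupper, "")
  alpha <- msa_alphabet(type)
  submat <- msa_submat(type)
  gaps <- if (type == "dna") c(5, 2) else c(11, 1)
  mats <- lapply(names(seqs), function(id) {
    matrix(strsplit(seqs[[id]], "")[[1]], nrow = 1,
           dimnames = list(id, NULL))
  })
  if (length(seqs) == 1L) return(mats[[1]])
  if (length(seqs) == 2L) {
    out <- merge_profiles(mats[[1]], mats[[2]], submat, alpha,
                          gaps[1], gaps[2])
    return(out[names(seqs), , drop = FALSE])
  }
  k <- if (type == "dna") 6L else 3L
  hc <- stats::hclust(stats::as.dist(kmer_guide_dist(seqs, k)),
                      method = "average")
  nodes <- vector("list", nrow(hc$merge))
  get_node <- function(v) if (v < 0) mats[[-v]] else nodes[[v]]
  for (s in seq_len(nrow(hc$merge))) {
    nodes[[s]] <- merge_profiles(get_node(hc$merge[s, 1]),
                                 get_node(hc$merge[s, 2]),
                                 submat, alpha, gaps[1], gaps[2])
  }
  out <- nodes[[length(nodes)]]
  out[names(seqs), , drop = FALSE]
}

#' Concatenate per-family alignments into a supermatrix
#'
#' Column-wise concatenation in the (fixed) order of `alignments`. Taxa
#' missing from a family are filled with gap blocks of that family's width.
#'
#' @param alignments named list of aligned character matrices (rows named
#'   by taxon).
#' @param taxa character vector of all taxa (row order of the result).
#' @return List with `matrix` (taxa x total columns) and `partitions`
#'   (data frame `family`, `start`, `end`, 1-based inclusive columns).
#' @export
concatenate_alignments <- function(alignments, taxa) {
  if (!length(alignments)) stop("no alignments to concatenate")
  if (is.null(names(alignments)))
    names(alignments) <- sprintf("fam%04d", seq_along(alignments))
  blocks <- vector("list", length(alignments))
  widths <- integer(length(alignments))
  for (i in seq_along(alignments)) {
    a <- alignments[[i]]
    if (anyDuplicated(rownames(a)))
      stop("duplicate taxon in family '", names(alignments)[i], "'")
    if (!all(rownames(a) %in% taxa))
      stop("unknown taxon in family '", names(alignments)[i], "'")
    w <- ncol(a)
    block <- matrix("-", length(taxa), w, dimnames = list(taxa, NULL))
    block[rownames(a), ] <- a
    blocks[[i]] <- block
    widths[i] <- w
  }
  ends <- cumsum(widths)
  list(matrix = do.call(cbind, blocks),
       partitions = data.frame(family = names(alignments),
                               start = c(1L, head(ends, -1) + 1L),
                               end = ends, stringsAsFactors = FALSE))
}
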