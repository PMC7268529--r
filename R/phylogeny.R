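## Distance matrices, Saitou-Nei neighbor joining with deterministic
## tie-breaks, and column-resampling bootstrap supports.

#' Pairwise distance matrix from a nucleotide alignment
#'
#' Pairwise-deletion distances over columns where both taxa carry an
#' unambiguous base. `p_distance` is the mismatch proportion; the
#' `jukes_cantor` model applies `d = -(3/4) log(1 - 4p/3)`.
#'
#' @param msa aligned character matrix (taxa x columns) or named character
#'   vector of equal-length gapped sequences.
#' @param model `"p_distance"` (default) or `"jukes_cantor"`.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(msa, model = c("p_distance", "jukes_cantor")) {
  model <- match.arg(model)
  if (!is.matrix(msa)) {
    msa <- do.call(rbind, strsplit(vapply(msa, toupper, ""), ""))
  }
  n <- nrow(msa)
  if (n < 2L) stop("need at least two taxa")
  valid <- matrix(msa %in% .BASES, nrow = n)
  d <- matrix(0, n, n, dimnames = list(rownames(msa), rownames(msa)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      comp <- valid[i, ] & valid[j, ]
      nc <- sum(comp)
      if (nc == 0L)
        stop("taxa ", i, " and ", j, " share no comparable columns")
      p <- sum(msa[i, comp] != msa[j, comp]) / nc
      dij <- if (model == "jukes_cantor") jukes_cantor(p) else p
      if (is.na(dij)) dij <- 3  # saturated JC distance capped
      d[i, j] <- d[j, i] <- dij
    }
  }
  d
}

#' Neighbor-joining tree (Saitou & Nei)
#'
#' Iteratively joins the pair minimizing
#' `Q(i,j) = (n-2) d(i,j) - R_i - R_j`; ties are broken by the
#' lexicographically smallest taxon-label pair. Negative branch-length
#' estimates are clamped to zero. Branch lengths are in the units of the
#' input distances (substitutions per site for sequence distances).
#'
#' @param d symmetric distance matrix with >= 3 labelled taxa.
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(d) {
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  if (nrow(d) < 3L) stop("need at least 3 taxa")
  labels <- rownames(d)
  newick <- labels          # newick fragment per active node
  first <- labels           # lexicographic key for tie-breaking
  D <- d
  bl <- function(x) sprintf("%.12g", max(0, x))
  while (nrow(D) > 3L) {
    n <- nrow(D)
    R <- rowSums(D)
    Q <- (n - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    hits <- which(Q - qmin < 1e-12, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    key <- paste(pmin(first[hits[, 1]], first[hits[, 2]]),
                 pmax(first[hits[, 1]], first[hits[, 2]]))
    pick <- hits[order(key)[1], ]
    i <- pick[1]; j <- pick[2]
    vi <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (n - 2))
    vj <- D[i, j] - vi
    new_nwk <- sprintf("(%s:%s,%s:%s)", newick[i], bl(vi), newick[j], bl(vj))
    new_first <- min(first[i], first[j])
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
                c(du[keep], 0))
    newick <- c(newick[keep], new_nwk)
    first <- c(first[keep], new_first)
    dimnames(D2) <- NULL
    D <- D2
  }
  ## final three nodes: closed-form three-point branch lengths
  x <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  y <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  z <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", newick[1], bl(x), newick[2], bl(y),
                 newick[3], bl(z))
  ape::read.tree(text = nwk)
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and reports for each internal edge of the point-estimate tree
#' the percentage of replicates containing the same bipartition.
#'
#' @param msa aligned character matrix (taxa x columns).
#' @param n_reps number of bootstrap replicates (default 1000).
#' @param seed integer seed (replicates are reproducible per seed).
#' @param model distance model passed to [distance_matrix()].
#' @return The point-estimate `phylo` tree with `node.label` set to
#'   bootstrap percentages (root label empty).
#' @export
bootstrap_support <- function(msa, n_reps = 1000, seed = 1,
                              model = "p_distance") {
  stopifnot(n_reps >= 1)
  point <- nj_tree(distance_matrix(msa, model = model))
  boots <- with_rng_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      cols <- sample.int(ncol(msa), ncol(msa), replace = TRUE)
      nj_tree(distance_matrix(msa[, cols, drop = FALSE], model = model))
    })
  })
  counts <- ape::prop.clades(point, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  supp <- round(100 * counts / n_reps, 1)
  point$node.label <- as.character(supp)
  point$node.label[1] <- ""   # root of the unrooted representation
  point
}
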