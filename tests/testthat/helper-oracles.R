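## Independent oracle implementations used to cross-check the package.
## These are deliberately written as plain enumerations / naive dynamic
## programs, sharing no code with the implementation under test.

GC <- Biostrings::GENETIC_CODE
SENSE_CODONS <- names(GC)[GC != "*"]
STOP_CODONS <- names(GC)[GC == "*"]

rand_cds <- function(n_codons, seed) {
  withr::with_seed(seed,
    paste(sample(SENSE_CODONS, n_codons, replace = TRUE), collapse = ""))
}

## --- NG86 oracle: explicit enumeration -------------------------------

oracle_site_fraction <- function(codon) {
  total <- 0
  for (pos in 1:3) {
    syn <- 0; nonstop <- 0
    for (b in c("A", "C", "G", "T")) {
      if (b == substr(codon, pos, pos)) next
      mut <- codon
      substr(mut, pos, pos) <- b
      if (GC[[mut]] == "*") next
      nonstop <- nonstop + 1
      if (GC[[mut]] == GC[[codon]]) syn <- syn + 1
    }
    if (nonstop > 0) total <- total + syn / nonstop
  }
  total
}

oracle_differences <- function(a, b) {
  diffs <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  k <- length(diffs)
  if (k == 0) return(c(0, 0))
  orderings <- if (k == 1) list(diffs) else
    lapply(seq_len(factorial(k)), function(i) diffs[perm_index(k, i)])
  paths <- list()
  for (ord in orderings) {
    cur <- a
    sd <- 0; nd <- 0; through_stop <- FALSE
    for (s in seq_along(ord)) {
      nxt <- cur
      substr(nxt, ord[s], ord[s]) <- substr(b, ord[s], ord[s])
      if (s < length(ord) && GC[[nxt]] == "*") through_stop <- TRUE
      if (GC[[cur]] == GC[[nxt]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    paths[[length(paths) + 1]] <- list(sd = sd, nd = nd, stop = through_stop)
  }
  ok <- !vapply(paths, `[[`, TRUE, "stop")
  if (!any(ok)) ok <- rep(TRUE, length(paths))
  c(mean(vapply(paths[ok], `[[`, 0, "sd")),
    mean(vapply(paths[ok], `[[`, 0, "nd")))
}

## i-th permutation of 1..k (k <= 3), by brute force
perm_index <- function(k, i) {
  all_perms <- switch(k,
    list(1),
    list(c(1, 2), c(2, 1)),
    list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
         c(3, 1, 2), c(3, 2, 1)))
  all_perms[[i]]
}

## --- alignment oracles: naive affine-gap DP --------------------------

## global (Needleman-Wunsch/Gotoh) score only, first gap position costs
## `open`, each further position `ext`
oracle_global_score <- function(a, b, submat, open, ext) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e18
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -open - ext * (i - 2)
  for (j in 2:(m + 1)) Y[1, j] <- -open - ext * (j - 2)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) +
        submat[a[i - 1], b[j - 1]]
      X[i, j] <- max(M[i - 1, j] - open, X[i - 1, j] - ext)
      Y[i, j] <- max(M[i, j - 1] - open, Y[i, j - 1] - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

## local (Smith-Waterman) best score with Biostrings-style gap cost
## (a gap of length L costs open + L * ext)
oracle_local_score <- function(a, b, submat, open, ext) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e18
  M <- X <- Y <- matrix(0, n + 1, m + 1)
  X[] <- NEG; Y[] <- NEG
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      M[i, j] <- max(0, max(M[i - 1, j - 1], X[i - 1, j - 1],
                            Y[i - 1, j - 1]) +
                        submat[a[i - 1], b[j - 1]])
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
      best <- max(best, M[i, j])
    }
  }
  best
}

## score an existing pairwise alignment (rows of a character matrix) under
## package conventions: first gap position costs open, further ext
score_pairwise_alignment <- function(row_a, row_b, submat, open, ext) {
  sc <- 0
  in_gap_a <- FALSE; in_gap_b <- FALSE
  for (k in seq_along(row_a)) {
    x <- row_a[k]; y <- row_b[k]
    if (x == "-") {
      sc <- sc - if (in_gap_a) ext else open
      in_gap_a <- TRUE; in_gap_b <- FALSE
    } else if (y == "-") {
      sc <- sc - if (in_gap_b) ext else open
      in_gap_b <- TRUE; in_gap_a <- FALSE
    } else {
      sc <- sc + submat[x, y]
      in_gap_a <- in_gap_b <- FALSE
    }
  }
  sc
}

## --- Fisher oracle: enumerate tables with fixed margins --------------

oracle_fisher_two_sided <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  probs <- vapply(0:min(r1, c1), function(x) {
    rest <- c1 - x
    if (rest < 0 || rest > r2) return(NA_real_)
    stats::dhyper(x, r1, r2, c1)
  }, 0)
  probs <- probs[!is.na(probs)]
  p_obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

## --- minimal independent MCL (dense, no pruning) ---------------------

oracle_mcl <- function(adj, inflation = 2, iters = 100) {
  diag(adj) <- apply(adj, 2, max)
  M <- sweep(adj, 2, colSums(adj), "/")
  for (i in seq_len(iters)) {
    M <- M %*% M
    M <- M^inflation
    M <- sweep(M, 2, colSums(M), "/")
  }
  keep <- M > 1e-8
  g <- igraph::graph_from_adjacency_matrix(keep, mode = "max", diag = FALSE)
  split(rownames(adj), igraph::components(g)$membership)
}

## --- misc ------------------------------------------------------------

## UTR alphabet restricted to C/T: cannot contain ATG or a stop on either
## strand, so a planted ORF stays the unique qualifying one
rand_utr <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("C", "T"), n, TRUE), collapse = ""))
}

small_fixture <- function(seed = 11, paralogs = 30) {
  generate_fixture(fixture_config(
    n_shared_single_copy = 20, n_shared_multi_copy = 5,
    n_species_specific = 6, gene_length = 150,
    n_paralog_pairs = paralogs, seed = seed))
}
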