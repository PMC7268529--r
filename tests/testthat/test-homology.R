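aa_letters <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                "M", "F", "P", "S", "T", "W", "Y", "V")

rand_prot <- function(n, seed) {
  withr::with_seed(seed, paste(sample(aa_letters, n, TRUE), collapse = ""))
}

blosum62 <- local({
  e <- new.env()
  data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

test_that("identical proteins give a full-identity self edge", {
  p <- rand_prot(200, seed = 1)
  e <- pairwise_similarity(c(x = p), c(y = p))
  expect_equal(e$identity, 1.0)
  expect_equal(e$aligned_len, 200)
  expect_lt(e$evalue_proxy, 1e-7)
})

test_that("local alignment score equals a brute-force DP oracle", {
  cases <- list(c("HEAGAWGHEE", "PAWHEAE"),
                c(rand_prot(40, 2), rand_prot(35, 3)),
                c(rand_prot(60, 4), rand_prot(60, 5)))
  for (cs in cases) {
    e <- pairwise_similarity(c(a = cs[1]), c(b = cs[2]), evalue_max = Inf)
    expect_equal(e$score,
                 oracle_local_score(cs[1], cs[2], blosum62, 11, 1))
  }
})

test_that("unrelated random proteins rarely pass the homology threshold", {
  n_edges <- 0
  for (i in 1:100) {
    e <- pairwise_similarity(c(a = rand_prot(200, 1000 + i)),
                             c(b = rand_prot(200, 2000 + i)))
    if (!is.null(e)) n_edges <- n_edges + 1
  }
  expect_lte(n_edges, 1)
})

test_that("non-amino-acid characters are rejected", {
  expect_error(pairwise_similarity(c(a = "MKV8"), c(b = "MKV")), "position 4")
})

test_that("MCL separates disconnected and weakly joined groups", {
  tri <- function(v, w = 1) data.frame(
    gene_a = v[c(1, 1, 2)], gene_b = v[c(2, 3, 3)], score = w)
  ## two disconnected triangles never merge
  cl <- mcl_cluster(rbind(tri(c("a", "b", "c")), tri(c("d", "e", "f"))))
  expect_equal(cl, list(c("a", "b", "c"), c("d", "e", "f")))
  ## a single edge is one cluster of two
  expect_equal(mcl_cluster(data.frame(gene_a = "a", gene_b = "b", score = 1)),
               list(c("a", "b")))
  ## no edges: every gene a singleton
  empty <- data.frame(gene_a = character(0), gene_b = character(0),
                      score = numeric(0))
  expect_equal(mcl_cluster(empty, genes = c("x", "y")),
               list("x", "y"))
})

test_that("barbell graph splits into its two cliques at inflation 2", {
  clique <- function(v, w) {
    p <- t(combn(v, 2))
    data.frame(gene_a = p[, 1], gene_b = p[, 2], score = w)
  }
  edges <- rbind(clique(paste0("a", 1:5), 1.0),
                 clique(paste0("b", 1:5), 1.0),
                 data.frame(gene_a = "a1", gene_b = "b1", score = 0.1))
  got <- mcl_cluster(edges, inflation = 2)
  ## independent dense MCL on the same adjacency
  genes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  adj <- matrix(0, 10, 10, dimnames = list(genes, genes))
  adj[cbind(edges$gene_a, edges$gene_b)] <- edges$score
  adj <- pmax(adj, t(adj))
  want <- unname(lapply(oracle_mcl(adj), sort))
  want <- want[order(vapply(want, `[[`, "", 1))]
  expect_equal(got, want)
  expect_length(got, 2)
  expect_equal(lengths(got), c(5L, 5L))
})

test_that("cluster partition covers every gene exactly once", {
  fx <- small_fixture(seed = 31, paralogs = 10)
  coding <- resolve_coding_set(fx$unigenes)
  prots <- setNames(coding$protein, coding$unigene_id)
  edges <- homology_edges(prots)
  cl <- mcl_cluster(edges, genes = names(prots))
  members <- unlist(cl)
  expect_equal(sort(members), sort(names(prots)))
  expect_false(anyDuplicated(members) > 0)
})

test_that("copy classes and Venn counts follow the membership rules", {
  fams <- list(c("a", "b", "c"), c("a1", "a2", "b", "c"), c("x1", "x2"),
               c("p", "q"))
  sp <- c(a = "T1", b = "T2", c = "T3", a1 = "T1", a2 = "T1", x1 = "T1",
          x2 = "T1", p = "T2", q = "T3")
  gf <- classify_families(fams, sp)
  cls <- gf$copy_class[!duplicated(gf$family_id)]
  expect_identical(cls, c("shared_single_copy", "shared_multi_copy",
                          "species_specific", "partial_shared"))
  v <- venn_counts(gf)
  expect_equal(sum(v$n_families), length(fams))
  expect_equal(sum(v$n_genes), length(unlist(fams)))
  expect_equal(v$n_genes[v$region == "T1"], 2)
  expect_equal(v$n_families[v$region == "T1"], 1)
  expect_equal(v$n_families[v$region == "T1&T2&T3"], 2)
  expect_error(classify_families(list("zz"), sp), "unknown gene")
})
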