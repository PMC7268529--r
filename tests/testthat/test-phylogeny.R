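dna_submat <- local({
  m <- matrix(-3, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                        c("A", "C", "G", "T")))
  diag(m) <- 2
  m
})

rand_dna <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = ""))
}

test_that("identical sequences align without gaps", {
  s <- rand_dna(80, 1)
  a <- progressive_align(c(x = s, y = s, z = s), type = "dna")
  expect_equal(ncol(a), 80)
  expect_false(any(a == "-"))
})

test_that("two-sequence alignment score equals a global DP oracle", {
  for (seed in 1:4) {
    s1 <- rand_dna(50, seed)
    s2 <- rand_dna(45, seed + 100)
    a <- progressive_align(c(a = s1, b = s2), type = "dna")
    got <- score_pairwise_alignment(a["a", ], a["b", ], dna_submat, 5, 2)
    expect_equal(got, oracle_global_score(s1, s2, dna_submat, 5, 2))
  }
})

test_that("alignment length is at least the longest input", {
  seqs <- c(a = rand_dna(60, 7), b = rand_dna(75, 8), c = rand_dna(50, 9))
  a <- progressive_align(seqs, type = "dna")
  expect_gte(ncol(a), 75)
  ## rows reproduce the inputs when gaps are removed
  for (id in names(seqs))
    expect_identical(paste(a[id, ][a[id, ] != "-"], collapse = ""),
                     seqs[[id]])
})

test_that("concatenation is additive and fills missing taxa with gaps", {
  m1 <- matrix("A", 2, 10, dimnames = list(c("s1", "s2"), NULL))
  m2 <- matrix("C", 2, 20, dimnames = list(c("s1", "s3"), NULL))
  m3 <- matrix("G", 3, 30, dimnames = list(c("s1", "s2", "s3"), NULL))
  sm <- concatenate_alignments(list(f1 = m1, f2 = m2, f3 = m3),
                               taxa = c("s1", "s2", "s3"))
  expect_equal(ncol(sm$matrix), 60)
  expect_true(all(sm$matrix["s2", 11:30] == "-"))
  expect_equal(sm$partitions$start, c(1, 11, 31))
  sm2 <- concatenate_alignments(list(f1 = m1, f2 = m2, f3 = m3),
                                taxa = c("s1", "s2", "s3"))
  expect_identical(sm, sm2)
  expect_error(
    concatenate_alignments(list(bad = rbind(m1, m1[1, , drop = FALSE])),
                           taxa = c("s1", "s2")),
    "duplicate taxon")
})

test_that("distances are symmetric with the JC closed form", {
  msa <- rbind(a = strsplit(strrep("A", 100), "")[[1]],
               b = strsplit(paste0(strrep("A", 90), strrep("C", 10)),
                            "")[[1]])
  d <- distance_matrix(msa)
  expect_equal(d["a", "b"], 0.1)
  expect_equal(d, t(d))
  expect_equal(diag(d), c(a = 0, b = 0))
  dj <- distance_matrix(msa, model = "jukes_cantor")
  expect_equal(dj["a", "b"], 0.10733, tolerance = 1e-4)
  expect_equal(distance_matrix(rbind(a = c("A", "C"), b = c("A", "C")))[1, 2],
               0)
})

test_that("permuting family order leaves the distance matrix unchanged", {
  m1 <- matrix(sample(c("A", "C", "G", "T"), 30, TRUE), 3, 10,
               dimnames = list(c("x", "y", "z"), NULL))
  m2 <- matrix(sample(c("A", "C", "G", "T"), 45, TRUE), 3, 15,
               dimnames = list(c("x", "y", "z"), NULL))
  d12 <- distance_matrix(concatenate_alignments(list(a = m1, b = m2),
                                                c("x", "y", "z"))$matrix)
  d21 <- distance_matrix(concatenate_alignments(list(b = m2, a = m1),
                                                c("x", "y", "z"))$matrix)
  expect_equal(d12, d21)
})

test_that("NJ recovers additive trees exactly", {
  ## 4 taxa: tree ((A:1,B:2):2,C:4,D:5) in unrooted form
  d4 <- matrix(c(0, 3, 7, 8,
                 3, 0, 8, 9,
                 7, 8, 0, 9,
                 8, 9, 9, 0), 4, 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- nj_tree(d4)
  ct <- ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(ct, d4, tolerance = 1e-9)
  ## AB|CD split present
  splits <- ape::prop.part(ape::unroot(tr))
  expect_true(any(vapply(splits, function(s)
    setequal(tr$tip.label[s], c("A", "B")) ||
      setequal(tr$tip.label[s], c("C", "D")), TRUE)))
})

test_that("three taxa use the closed-form three-point branch lengths", {
  d <- matrix(c(0, 5, 9, 5, 0, 8, 9, 8, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  el <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(el[["a"]], (5 + 9 - 8) / 2)
  expect_equal(el[["b"]], (5 + 8 - 9) / 2)
  expect_equal(el[["c"]], (9 + 8 - 5) / 2)
})

test_that("NJ matches the reference implementation on random matrices", {
  for (seed in 1:3) {
    d <- withr::with_seed(seed, {
      x <- matrix(runif(36, 0.1, 1), 6, 6)
      x <- (x + t(x)) / 2
      diag(x) <- 0
      dimnames(x) <- list(letters[1:6], letters[1:6])
      x
    })
    mine <- nj_tree(d)
    ref <- ape::nj(as.dist(d))
    expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(ref)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("equidistant taxa yield a zero-length internal edge", {
  d <- matrix(1, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(d) <- 0
  tr <- nj_tree(d)
  internal <- tr$edge[, 2] > length(tr$tip.label)
  expect_true(all(abs(tr$edge.length[internal]) < 1e-12))
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric|3 taxa")
})

test_that("bootstrap supports are reproducible and bounded", {
  ## two clean clades with ~20% between-clade divergence
  base1 <- rand_dna(1000, 11)
  base2 <- local({
    b <- strsplit(base1, "")[[1]]
    idx <- withr::with_seed(12, sample(1000, 200))
    b[idx] <- vapply(b[idx], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
    paste(b, collapse = "")
  })
  jitter <- function(s, n, seed) {
    b <- strsplit(s, "")[[1]]
    idx <- withr::with_seed(seed, sample(length(b), n))
    b[idx] <- vapply(b[idx], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
    paste(b, collapse = "")
  }
  seqs <- c(a1 = jitter(base1, 10, 21), a2 = jitter(base1, 10, 22),
            b1 = jitter(base2, 10, 23), b2 = jitter(base2, 10, 24))
  msa <- do.call(rbind, strsplit(seqs, ""))
  t1 <- bootstrap_support(msa, n_reps = 200, seed = 42)
  t2 <- bootstrap_support(msa, n_reps = 200, seed = 42)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  supp <- suppressWarnings(as.numeric(t1$node.label))
  supp <- supp[!is.na(supp)]
  expect_true(all(supp >= 0 & supp <= 100))
  ## the clade split carries essentially full support
  expect_gte(max(supp), 99)
})
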