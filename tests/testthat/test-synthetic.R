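test_that("zero targets leave the sequence untouched", {
  cds <- rand_cds(100, seed = 1)
  expect_identical(mutate_to_target(cds, 0, 0, seed = 5), cds)
})

test_that("mutation is deterministic per seed and rejects bad input", {
  cds <- rand_cds(200, seed = 2)
  expect_identical(mutate_to_target(cds, 0.1, 0.3, seed = 7),
                   mutate_to_target(cds, 0.1, 0.3, seed = 7))
  expect_false(identical(mutate_to_target(cds, 0.1, 0.3, seed = 7),
                         mutate_to_target(cds, 0.1, 0.3, seed = 8)))
  expect_error(mutate_to_target("ATGTAAATG", 0.1, 0.1), "stop codon")
  expect_error(mutate_to_target(cds, Inf, 0.1), "finite")
  ## no stop codons are ever introduced
  mut <- mutate_to_target(cds, 0.5, 1.5, seed = 9)
  expect_false(any(strsplit(gsub("(...)", "\\1 ", mut), " ")[[1]] %in%
                     c("TAA", "TAG", "TGA")))
})

test_that("round-trip targets are recovered across the (Ka, Ks) grid", {
  ## tolerances: 15% relative with a small absolute floor for Poisson
  ## counting noise at tiny expected hit counts; 25% for targets >= 1,
  ## where NG86 pathway counting is systematically downward-biased as
  ## within-codon multiple hits approach saturation
  root <- rand_cds(3000, seed = 3)
  grid <- expand.grid(ks = c(0.05, 0.1, 0.3, 0.5, 1.0),
                      ratio = c(0.05, 0.3, 0.7, 1.5))
  tol <- function(target) max(ifelse(target >= 1, 0.25, 0.15) * target, 0.005)
  for (g in seq_len(nrow(grid))) {
    ks <- grid$ks[g]
    ka <- ks * grid$ratio[g]
    mut <- mutate_to_target(root, ka, ks, seed = 100 + g)
    st <- kaks_pair(c(a = root, b = mut))
    expect_lt(abs(st$Ks - ks), tol(ks))
    expect_lt(abs(st$Ka - ka), tol(ka))
  }
})

test_that("a strongly selected pair round-trips to Ka/Ks > 1", {
  root <- rand_cds(3000, seed = 4)
  mut <- mutate_to_target(root, 0.2, 0.11, seed = 2)
  st <- kaks_pair(c(a = root, b = mut))
  expect_gt(st$kaks, 1)
  expect_identical(classify_selection(st), "strong_positive")
})

test_that("mixture samples respect truncation and the law of large numbers", {
  one <- cbind(1.0, 0.5, 0.05)
  x <- simulate_ks_sample(one, 10000, seed = 11)
  expect_lt(abs(mean(x) - 0.5), 0.01)
  expect_true(all(x > 0 & x <= 2))
  expect_identical(simulate_ks_sample(one, 50, seed = 1),
                   simulate_ks_sample(one, 50, seed = 1))
  expect_error(simulate_ks_sample(matrix(nrow = 0, ncol = 3), 10), "empty")
})

test_that("fixture counts, determinism, and class recovery hold", {
  cfg <- fixture_config(n_shared_single_copy = 30, n_shared_multi_copy = 6,
                        n_species_specific = 10, gene_length = 150,
                        n_paralog_pairs = 0, seed = 51)
  fx <- generate_fixture(cfg)
  fams <- fx$families
  cls <- fams$copy_class[!duplicated(fams$family_id)]
  expect_equal(sum(cls == "shared_single_copy"), 30)
  expect_equal(sum(cls == "shared_multi_copy"), 6)
  expect_equal(sum(cls == "species_specific"), 30)
  expect_equal(nrow(fx$unigenes), 30 * 3 + 6 * 4 + 30)
  expect_equal(sort(unique(fx$unigenes$species)), c("T1", "T2", "T3"))
  expect_false(anyDuplicated(fx$unigenes$id) > 0)
  ## truth tables cover all generated ortholog pairs
  expect_equal(nrow(fx$ortholog_truth), 30 * 3)

  ## same config + seed: byte-identical FASTA output
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_fixture(cfg, out_dir = d1)
  generate_fixture(cfg, out_dir = d2)
  for (f in c("T1.fasta", "T2.fasta", "T3.fasta", "annotation.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }

  ## end-to-end family recovery: clustered families match planted truth
  coding <- resolve_coding_set(fx$unigenes)
  prots <- setNames(coding$protein, coding$unigene_id)
  clusters <- mcl_cluster(homology_edges(prots), genes = names(prots))
  truth <- lapply(split(fams$gene_id, fams$family_id), sort)
  got <- lapply(clusters, sort)
  recovered <- sum(vapply(truth, function(tf)
    any(vapply(got, identical, TRUE, tf)), TRUE))
  expect_gte(recovered / length(truth), 0.95)
})
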