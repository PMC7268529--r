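test_that("site fractions match hand-enumerated degeneracies", {
  expect_equal(ng86_site_fraction("TTT"), 1 / 3)
  expect_equal(ng86_site_fraction("GGG"), 1)
  expect_equal(ng86_site_fraction("ATG"), 0)
  expect_error(ng86_site_fraction("TAA"), "sense codon")
})

test_that("pathway-averaged differences handle 1- and 2-step pairs", {
  expect_equal(unname(ng86_differences("TTT", "TTC")), c(1, 0))
  expect_equal(unname(ng86_differences("TTT", "GTT")), c(0, 1))
  ## two pathways: via GTT (1 nonsyn + 1 syn) and via TTA (2 nonsyn)
  expect_equal(unname(ng86_differences("TTT", "GTA")), c(0.5, 1.5))
})

test_that("NG86 tables agree with exhaustive enumeration on a sample", {
  withr::with_seed(1, {
    codons <- sample(SENSE_CODONS, 12)
    for (cod in codons)
      expect_equal(ng86_site_fraction(cod), oracle_site_fraction(cod))
    for (i in 1:20) {
      pair <- sample(SENSE_CODONS, 2)
      expect_equal(unname(ng86_differences(pair[1], pair[2])),
                   oracle_differences(pair[1], pair[2]))
    }
  })
})

test_that("Jukes-Cantor correction matches the closed form and saturates", {
  expect_equal(jukes_cantor(0), 0)
  expect_equal(jukes_cantor(0.1), 0.10733, tolerance = 1e-4)
  expect_true(is.na(jukes_cantor(0.75)))
  expect_error(jukes_cantor(-0.1))
})

test_that("back-translation maps residues to codons and gaps to gap codons", {
  cds <- list(a = "ATGTTTGGG", b = "ATGGGGTAA")
  aln <- c(a = "MFG", b = "M-G")
  bt <- back_translate(aln, cds)
  expect_identical(unname(bt[["a"]]), "ATGTTTGGG")
  expect_identical(unname(bt[["b"]]), "ATG---GGG")  # trailing stop dropped
  expect_error(back_translate(c(a = "MFF"), list(a = "ATGTTTGGG")),
               "residue 3")
})

test_that("Ka/Ks of identical sequences is zero with undefined ratio", {
  cds <- rand_cds(200, seed = 2)
  st <- kaks_pair(c(a = cds, b = cds))
  expect_equal(st$Ka, 0)
  expect_equal(st$Ks, 0)
  expect_true(is.na(st$kaks))
  expect_equal(st$fisher_p, 1)
})

test_that("site counts conserve S + N = 3 x codon columns and are symmetric", {
  a <- rand_cds(300, seed = 5)
  b <- mutate_to_target(a, 0.05, 0.4, seed = 6)
  st_ab <- kaks_pair(c(a = a, b = b))
  st_ba <- kaks_pair(c(b = b, a = a))
  expect_equal(st_ab$S + st_ab$N, 3 * 300)
  for (col in c("S", "N", "Sd", "Nd", "Ka", "Ks", "kaks", "fisher_p"))
    expect_equal(st_ab[[col]], st_ba[[col]])
})

test_that("round-trip estimation recovers generator targets", {
  a <- rand_cds(3000, seed = 7)
  b <- mutate_to_target(a, 0.03, 0.30, seed = 8)
  st <- kaks_pair(c(a = a, b = b))
  expect_lt(abs(st$Ka - 0.03) / 0.03, 0.15)
  expect_lt(abs(st$Ks - 0.30) / 0.30, 0.15)
})

test_that("fully saturated synonymous sites flag Ks as not applicable", {
  ## every codon pair differs at a fourfold-degenerate third position more
  ## than 75% of the time: force p = 1 with an alternating GGG/GGC pattern
  a <- strrep("GGG", 120)
  b <- strrep("GGC", 120)
  st <- kaks_pair(c(a = a, b = b))
  expect_true(is.na(st$Ks))
  expect_true(is.na(st$kaks))
})

test_that("the Fisher gate matches exhaustive fixed-margin enumeration", {
  expect_equal(fisher_gate(10, 30, 0, 0), 1)
  cases <- list(c(10, 30, 5, 1), c(20, 60, 1, 3), c(50, 150, 10, 4),
                c(12, 40, 3, 9))
  for (cs in cases) {
    tab <- matrix(c(cs[3], cs[1] - cs[3], cs[4], cs[2] - cs[4]),
                  nrow = 2, byrow = TRUE)
    expect_equal(fisher_gate(cs[1], cs[2], cs[3], cs[4]),
                 oracle_fisher_two_sided(tab), tolerance = 1e-10)
  }
  ## proportional table: no table with the same margins is less probable
  expect_equal(fisher_gate(20, 60, 1, 3), 1.0)
  expect_error(fisher_gate(-1, 10, 0, 0))
})

test_that("selection classes follow the threshold bins with Ks filtering", {
  mk <- function(ka, ks) data.frame(Ka = ka, Ks = ks,
                                    kaks = ifelse(ks > 0, ka / ks, NA))
  expect_identical(classify_selection(mk(0.6, 0.4)), "strong_positive")
  expect_identical(classify_selection(mk(0.28, 0.4)), "weak_positive")
  expect_identical(classify_selection(mk(0.12, 0.4)), "neutral")
  expect_identical(classify_selection(mk(0.02, 0.4)), "purifying")
  expect_identical(classify_selection(mk(0.035, 0.05)), "excluded")
  expect_identical(classify_selection(data.frame(Ka = 0.1, Ks = NA,
                                                 kaks = NA)), "excluded")
  ## boundary conventions: ratio exactly 1 -> weak; 0.5 and 0.1 -> neutral
  mkr <- function(r) data.frame(Ka = r, Ks = 1, kaks = r)
  expect_identical(classify_selection(mkr(1)), "weak_positive")
  expect_identical(classify_selection(mkr(0.5)), "neutral")
  expect_identical(classify_selection(mkr(0.1)), "neutral")
  ## Ka = 0 with applicable Ks stays purifying
  expect_identical(classify_selection(mk(0, 0.4)), "purifying")
  ## partition: every non-excluded pair gets exactly one class
  withr::with_seed(3, {
    df <- mk(runif(200, 0, 1), runif(200, 0, 1.5))
    cls <- classify_selection(df)
    expect_true(all(cls %in% c("strong_positive", "weak_positive", "neutral",
                               "purifying", "excluded")))
    expect_equal(sum(cls != "excluded"), sum(df$Ks > 0.1))
  })
})
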