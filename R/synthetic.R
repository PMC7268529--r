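## Synthetic transcript sets with the statistical structure the downstream
## stages assume: shared single-copy ortholog families evolved to target
## (Ka, Ks), multi-copy families, species-specific genes, within-species
## paralog pairs with mixture-distributed Ks, and planted enriched
## annotation terms.

#' Fixture generation configuration
#'
#' Defaults encode the study conditions the pipeline is exercised under:
#' three species, mostly purifying/neutral ortholog divergence with a few
#' positively selected pairs, and a truncated three-component Gaussian
#' mixture of paralog Ks values (recent, medium and ancient duplication
#' peaks).
#'
#' @param n_shared_single_copy single-copy families shared by all species.
#' @param n_shared_multi_copy multi-copy families shared by all species.
#' @param n_species_specific species-specific genes per species.
#' @param gene_length gene length in codons (>= 100 so the 300-nt paralog
#'   rule can trigger).
#' @param ortholog_ks_targets two-column matrix (Ka, Ks) of pairwise
#'   divergence targets, recycled across single-copy families.
#' @param paralog_mixture three-column matrix (weight, mu, sigma) of the
#'   paralog Ks mixture; weights must sum to 1.
#' @param n_paralog_pairs planted within-species duplicate pairs per
#'   species.
#' @param planted_terms data frame (`term_id`, `background_freq`,
#'   `enrichment_factor`) of annotation terms; the enrichment factor
#'   multiplies the annotation probability on the planted query set (genes
#'   of positively selected families).
#' @param seed integer seed.
#' @return A `fixture_config` list, validated.
#' @export
fixture_config <- function(n_shared_single_copy = 100,
                           n_shared_multi_copy = 20,
                           n_species_specific = 30,
                           gene_length = 200,
                           ortholog_ks_targets = default_ortholog_targets(),
                           paralog_mixture = default_paralog_mixture(),
                           n_paralog_pairs = 150,
                           planted_terms = default_planted_terms(),
                           seed = 1) {
  cfg <- list(n_shared_single_copy = n_shared_single_copy,
              n_shared_multi_copy = n_shared_multi_copy,
              n_species_specific = n_species_specific,
              gene_length = gene_length,
              ortholog_ks_targets = ortholog_ks_targets,
              paralog_mixture = paralog_mixture,
              n_paralog_pairs = n_paralog_pairs,
              planted_terms = planted_terms,
              seed = as.integer(seed))
  counts <- c(cfg$n_shared_single_copy, cfg$n_shared_multi_copy,
              cfg$n_species_specific, cfg$n_paralog_pairs)
  if (any(counts < 0)) stop("counts must be >= 0")
  if (cfg$gene_length < 100) stop("gene_length must be >= 100 codons")
  w <- cfg$paralog_mixture[, 1]
  if (abs(sum(w) - 1) > 1e-9) stop("mixture weights must sum to 1")
  if (any(cfg$paralog_mixture[, 3] <= 0)) stop("mixture sigmas must be > 0")
  class(cfg) <- "fixture_config"
  cfg
}

#' @rdname fixture_config
#' @export
default_ortholog_targets <- function() {
  ## (Ka, Ks) pairs spanning the selection classes, dominated by purifying
  ## and neutral divergence as observed in real single-copy ortholog sets
  cbind(Ka = c(0.010, 0.020, 0.015, 0.060, 0.090, 0.050, 0.280, 0.450,
               0.025, 0.008),
        Ks = c(0.300, 0.250, 0.400, 0.300, 0.250, 0.060, 0.350, 0.300,
               0.150, 0.200))
}

#' @rdname fixture_config
#' @export
default_paralog_mixture <- function() {
  ## recent / medium / ancient duplication peaks of a thrice-duplicated
  ## paranome; sigma grows with age as diploidization broadens old peaks
  cbind(weight = c(0.40, 0.35, 0.25),
        mu     = c(0.1144, 0.5281, 1.4347),
        sigma  = c(0.0678, 0.2294, 0.3103))
}

#' @rdname fixture_config
#' @export
default_planted_terms <- function() {
  data.frame(term_id = sprintf("TERM%04d", 1:8),
             background_freq = c(0.05, 0.05, 0.10, 0.10, 0.15, 0.20,
                                 0.08, 0.12),
             enrichment_factor = c(10, 8, 1, 1, 1, 1, 6, 1),
             stringsAsFactors = FALSE)
}

random_cds <- function(n_codons) {
  tabs <- genetic_code_tables()
  body <- sample(setdiff(tabs$sense, "ATG"), n_codons - 1L, replace = TRUE)
  paste(c("ATG", body), collapse = "")
}

## evolve a CDS but keep the start codon intact, so generated unigenes stay
## clean ORFs recoverable by the coding-region stage
mutate_body <- function(cds, ka, ks, seed) {
  paste0(substr(cds, 1L, 3L),
         mutate_to_target(substr(cds, 4L, nchar(cds)), ka, ks, seed))
}

#' Evolve a coding sequence to target Ka and Ks
#'
#' Applies per-site substitution probabilities obtained by inverting the
#' Jukes-Cantor correction at the targets
#' (`p = (3/4)(1 - exp(-4 d / 3))`): each codon position is hit
#' synonymously with probability `p_s f` and nonsynonymously with
#' probability `p_n (1 - f)`, where `f` is the position's synonymous site
#' fraction. Replacement bases are drawn uniformly from the non-stop
#' synonymous (resp. nonsynonymous) single-base mutants of the current
#' codon, so no internal stop codons are ever introduced.
#'
#' @param cds codon sequence (length divisible by 3, no internal stops).
#' @param target_ka,target_ks target rates, >= 0 and finite.
#' @param seed integer seed.
#' @return The mutated coding sequence.
#' @export
mutate_to_target <- function(cds, target_ka, target_ks, seed = 1) {
  if (!is.finite(target_ka) || !is.finite(target_ks) ||
      target_ka < 0 || target_ks < 0)
    stop("targets must be finite and >= 0 (saturating targets with ",
         "substitution probability >= 3/4 are not representable)")
  tabs <- genetic_code_tables()
  codons <- split_codons(toupper(cds))
  if (any(codons %in% .STOPS))
    stop("input contains a stop codon at codon ",
         which(codons %in% .STOPS)[1])
  if (!all(codons %in% tabs$sense)) stop("input contains non-sense codons")
  p_s <- 0.75 * (1 - exp(-4 * target_ks / 3))
  p_n <- 0.75 * (1 - exp(-4 * target_ka / 3))
  if (p_s == 0 && p_n == 0) return(paste(codons, collapse = ""))
  with_rng_seed(seed, {
    f <- t(tabs$site[codons, , drop = FALSE])       # 3 x n_codons
    u <- matrix(runif(length(f)), nrow = 3)
    syn_hit <- u < p_s * f
    non_hit <- !syn_hit & u < p_s * f + p_n * (1 - f)
    hit_cod <- which(colSums(syn_hit | non_hit) > 0)
    for (ci in hit_cod) {
      cur <- codons[ci]
      for (pos in 1:3) {
        if (!syn_hit[pos, ci] && !non_hit[pos, ci]) next
        cand <- tabs$mut[[cur]][[pos]][[if (syn_hit[pos, ci]) "syn"
                                        else "nonsyn"]]
        if (!length(cand)) next   # no legal mutant of that type; skip draw
        base <- cand[sample.int(length(cand), 1L)]
        substr(cur, pos, pos) <- base
      }
      codons[ci] <- cur
    }
  })
  paste(codons, collapse = "")
}

#' Sample Ks values from a truncated Gaussian mixture
#'
#' Draws from the mixture and accepts values inside the truncation interval
#' (rejection sampling, so within-interval component shapes are preserved).
#'
#' @param mixture matrix with columns (weight, mu, sigma).
#' @param n number of values.
#' @param truncation interval, default `(0, 2]`.
#' @param seed integer seed.
#' @return Numeric vector of `n` Ks values inside the truncation interval.
#' @export
simulate_ks_sample <- function(mixture, n, truncation = c(0, 2), seed = 1) {
  if (is.null(dim(mixture)) || nrow(mixture) == 0) stop("empty mixture")
  w <- mixture[, 1]; mu <- mixture[, 2]; sig <- mixture[, 3]
  if (abs(sum(w) - 1) > 1e-9) stop("mixture weights must sum to 1")
  if (any(sig <= 0)) stop("mixture sigmas must be > 0")
  with_rng_seed(seed, {
    out <- numeric(0)
    while (length(out) < n) {
      todo <- n - length(out)
      comp <- sample.int(length(w), size = 2 * todo + 10, replace = TRUE,
                         prob = w)
      x <- rnorm(length(comp), mu[comp], sig[comp])
      out <- c(out, x[x > truncation[1] & x <= truncation[2]])
    }
    out[seq_len(n)]
  })
}

#' Generate a three-species fixture transcript set
#'
#' Writes one FASTA per species (headers `>T{1|2|3}_gene{N}[_copy{M}]`), a
#' term-annotation TSV and a JSON truth manifest to `out_dir` (when given),
#' and returns everything in memory. Single-copy families carry exactly one
#' gene per species, evolved from a common ancestor so each species pair
#' meets a target (Ka, Ks) (each copy receives half the target). Multi-copy
#' families add a within-species duplicate; species-specific genes are
#' independent; paralog pairs are duplicates with Ks drawn from the
#' configured mixture and Ka = 0.2 Ks.
#'
#' @param config a [fixture_config()].
#' @param out_dir optional output directory (created if needed).
#' @return A `fixture_manifest` list: `unigenes` (data frame `id`,
#'   `species`, `seq`), `families` (truth: `family_id`, `gene_id`,
#'   `species`, `copy_class`), `ortholog_truth` (per single-copy family and
#'   species pair: target Ka, Ks), `paralog_truth` (per planted pair: true
#'   Ks), `annotation` (gene_id, term_id, ontology), `query_genes` (the
#'   planted enriched set), `config`, and `files` (paths, when written).
#' @export
generate_fixture <- function(config = fixture_config(), out_dir = NULL) {
  stopifnot(inherits(config, "fixture_config"))
  species <- c("T1", "T2", "T3")
  L <- config$gene_length
  targets <- config$ortholog_ks_targets
  gene_rows <- list()
  fam_rows <- list()
  orth_rows <- list()
  par_rows <- list()
  fam_i <- 0L
  add_gene <- function(id, sp, seq) {
    gene_rows[[length(gene_rows) + 1L]] <<- data.frame(
      id = id, species = sp, seq = seq, stringsAsFactors = FALSE)
  }
  add_fam <- function(fid, ids, sps, cls) {
    fam_rows[[length(fam_rows) + 1L]] <<- data.frame(
      family_id = fid, gene_id = ids, species = sps, copy_class = cls,
      stringsAsFactors = FALSE)
  }
  with_rng_seed(config$seed, {
    gene_n <- 0L
    ## shared single-copy families
    for (i in seq_len(config$n_shared_single_copy)) {
      fam_i <- fam_i + 1L
      gene_n <- gene_n + 1L
      tgt <- targets[((i - 1L) %% nrow(targets)) + 1L, ]
      root <- random_cds(L)
      seeds <- sample.int(2^30, 3)
      ids <- sprintf("%s_gene%04d", species, gene_n)
      for (s in 1:3) {
        seq_s <- mutate_body(root, tgt[1] / 2, tgt[2] / 2, seeds[s])
        add_gene(ids[s], species[s], seq_s)
      }
      add_fam(sprintf("SC%04d", i), ids, species, "shared_single_copy")
      for (pr in list(c(1, 2), c(1, 3), c(2, 3))) {
        orth_rows[[length(orth_rows) + 1L]] <- data.frame(
          family_id = sprintf("SC%04d", i),
          gene_a = ids[pr[1]], gene_b = ids[pr[2]],
          true_ka = unname(tgt[1]), true_ks = unname(tgt[2]),
          stringsAsFactors = FALSE)
      }
    }
    ## shared multi-copy families: one gene per species plus a duplicate in
    ## a rotating species at moderate divergence
    for (i in seq_len(config$n_shared_multi_copy)) {
      fam_i <- fam_i + 1L
      gene_n <- gene_n + 1L
      root <- random_cds(L)
      ids <- sprintf("%s_gene%04d", species, gene_n)
      seeds <- sample.int(2^30, 4)
      for (s in 1:3) {
        add_gene(ids[s], species[s],
                 mutate_body(root, 0.02, 0.12, seeds[s]))
      }
      dup_sp <- ((i - 1L) %% 3L) + 1L
      dup_id <- sprintf("%s_gene%04d_copy2", species[dup_sp], gene_n)
      add_gene(dup_id, species[dup_sp],
               mutate_body(root, 0.05, 0.30, seeds[4]))
      add_fam(sprintf("MC%04d", i), c(ids, dup_id),
              c(species, species[dup_sp]), "shared_multi_copy")
    }
    ## species-specific singletons
    for (s in 1:3) {
      for (i in seq_len(config$n_species_specific)) {
        fam_i <- fam_i + 1L
        gene_n <- gene_n + 1L
        id <- sprintf("%s_gene%04d", species[s], gene_n)
        add_gene(id, species[s], random_cds(L))
        add_fam(sprintf("SP%s%04d", species[s], i), id, species[s],
                "species_specific")
      }
    }
    ## planted paralog pairs: species-specific duplicate pairs with
    ## mixture-distributed Ks and purifying-dominated Ka = 0.2 Ks
    if (config$n_paralog_pairs > 0) {
      for (s in 1:3) {
        ks_draw <- simulate_ks_sample(config$paralog_mixture,
                                      config$n_paralog_pairs,
                                      seed = sample.int(2^30, 1))
        for (i in seq_len(config$n_paralog_pairs)) {
          fam_i <- fam_i + 1L
          gene_n <- gene_n + 1L
          root <- random_cds(L)
          id_a <- sprintf("%s_gene%04d", species[s], gene_n)
          id_b <- sprintf("%s_gene%04d_copy2", species[s], gene_n)
          add_gene(id_a, species[s], root)
          add_gene(id_b, species[s],
                   mutate_body(root, 0.2 * ks_draw[i], ks_draw[i],
                                    sample.int(2^30, 1)))
          add_fam(sprintf("PP%s%04d", species[s], i), c(id_a, id_b),
                  rep(species[s], 2), "species_specific")
          par_rows[[length(par_rows) + 1L]] <- data.frame(
            species = species[s], gene_a = id_a, gene_b = id_b,
            true_ks = ks_draw[i], stringsAsFactors = FALSE)
        }
      }
    }
    unigenes <- do.call(rbind, gene_rows)
    families <- do.call(rbind, fam_rows)
    ## annotation with planted enrichment on positively selected families
    pos_fams <- unique(unlist(lapply(orth_rows, function(r)
      if (r$true_ka / r$true_ks > 0.5) r$family_id else NULL)))
    query_genes <- sort(families$gene_id[families$family_id %in% pos_fams])
    ann_rows <- list()
    for (t in seq_len(nrow(config$planted_terms))) {
      term <- config$planted_terms[t, ]
      p_bg <- term$background_freq
      p_q <- min(1, p_bg * term$enrichment_factor)
      prob <- ifelse(unigenes$id %in% query_genes, p_q, p_bg)
      hit <- runif(nrow(unigenes)) < prob
      if (any(hit)) {
        ann_rows[[length(ann_rows) + 1L]] <- data.frame(
          gene_id = unigenes$id[hit], term_id = term$term_id,
          ontology = "synthetic", stringsAsFactors = FALSE)
      }
    }
    annotation <- do.call(rbind, ann_rows)
    annotation <- annotation[order(annotation$gene_id, annotation$term_id), ]
    rownames(annotation) <- NULL
    manifest <- list(unigenes = unigenes, families = families,
                     ortholog_truth = do.call(rbind, orth_rows),
                     paralog_truth = if (length(par_rows))
                       do.call(rbind, par_rows) else NULL,
                     annotation = annotation, query_genes = query_genes,
                     config = config)
    class(manifest) <- "fixture_manifest"
    if (!is.null(out_dir)) manifest$files <- write_fixture(manifest, out_dir)
    manifest
  })
}

write_fixture <- function(manifest, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  for (sp in unique(manifest$unigenes$species)) {
    sub <- manifest$unigenes[manifest$unigenes$species == sp, ]
    path <- file.path(out_dir, paste0(sp, ".fasta"))
    write_fasta(setNames(sub$seq, sub$id), path)
    files[[sp]] <- path
  }
  ann_path <- file.path(out_dir, "annotation.tsv")
  write_tsv(manifest$annotation, ann_path)
  files$annotation <- ann_path
  man_path <- file.path(out_dir, "manifest.json")
  m <- manifest[c("families", "ortholog_truth", "paralog_truth",
                  "query_genes")]
  jsonlite::write_json(m, man_path, dataframe = "columns", digits = NA,
                       pretty = TRUE)
  files$manifest <- man_path
  files
}

#' @export
print.fixture_manifest <- function(x, ...) {
  cat(sprintf("fixture_manifest: %d genes, %d families, %d annotations\n",
              nrow(x$unigenes), length(unique(x$families$family_id)),
              nrow(x$annotation)))
  invisible(x)
}
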