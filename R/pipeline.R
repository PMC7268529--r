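## End-to-end orchestration: coding regions -> homology graph -> families,
## then Ka/Ks + enrichment, supermatrix phylogeny, and paralog Ks dating.

#' Pipeline configuration
#'
#' Thresholds default to the standard values used throughout the package:
#' annotation e-value 1e-5, homology 1e-7, ortholog Ks filter 0.1, paralog
#' Ks cap 2.0, paralog identity 0.40 over >= 300 nt, Ks histogram
#' bandwidth 0.03, 1000 bootstrap replicates, 3 mixture components, and a
#' synonymous substitution rate of 6.1e-9 per site per year.
#'
#' @param fasta named list/vector of per-species FASTA paths (names are
#'   species tags), or `NULL` when `unigenes` are passed to
#'   [run_pipeline()] directly.
#' @param annotation optional annotation TSV path.
#' @param out_dir output directory for artifacts.
#' @param evalue_annotation,evalue_homology,ks_min_ortholog,ks_max_paralog,
#'   min_identity,min_aligned_nt,bandwidth,n_bootstrap,mixture_k,rate,
#'   min_orf_nt thresholds (see description).
#' @param seed master seed fanned out to per-stage seeds.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(fasta = NULL, annotation = NULL,
                            out_dir = tempfile("ploidtrace_run_"),
                            evalue_annotation = 1e-5,
                            evalue_homology = 1e-7,
                            ks_min_ortholog = 0.1,
                            ks_max_paralog = 2.0,
                            min_identity = 0.40,
                            min_aligned_nt = 300,
                            bandwidth = 0.03,
                            n_bootstrap = 1000,
                            mixture_k = 3,
                            rate = 6.1e-9,
                            min_orf_nt = 150,
                            seed = 1) {
  cfg <- as.list(environment())
  thresholds <- c(evalue_annotation, evalue_homology, ks_min_ortholog,
                  ks_max_paralog, min_identity, min_aligned_nt, bandwidth,
                  n_bootstrap, mixture_k, rate, min_orf_nt)
  if (any(thresholds <= 0)) stop("all thresholds must be positive")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full molecular-evolution pipeline
#'
#' Stages: coding-region identification, all-vs-all protein homology and
#' Markov clustering into families with Venn accounting, per-family
#' protein alignment + back-translation + NG86 Ka/Ks with Fisher gate and
#' selection classes for single-copy orthologs, hypergeometric enrichment
#' of the positively selected set, supermatrix NJ phylogeny with
#' bootstrap, and within-species paralog Ks dating (histogram, mixture
#' fit, ages). All artifacts are written under `config$out_dir`; the run
#' is deterministic given the seed.
#'
#' @param config a [pipeline_config()].
#' @param unigenes optional in-memory unigene data frame (`id`, `species`,
#'   `seq`), bypassing FASTA input.
#' @param hits optional annotation hit table (see [resolve_coding()]).
#' @param annotation optional in-memory annotation data frame.
#' @return A `run_report` list: per-stage records (counts in/out/removed,
#'   parameters) plus the key results (`families`, `venn`, `kaks`,
#'   `tree`, `enrichment`, `wgd_fit`) and artifact paths.
#' @export
run_pipeline <- function(config = pipeline_config(), unigenes = NULL,
                         hits = NULL, annotation = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  report <- list(stages = list(), params = config[!(names(config) %in%
                                                     c("fasta", "annotation"))])
  stage <- function(name, n_in, n_out, params = list()) {
    report$stages[[name]] <<- list(name = name, n_in = n_in, n_out = n_out,
                                   n_removed = n_in - n_out, params = params)
  }
  fail <- function(name, e) stop("pipeline stage '", name, "' failed: ",
                                 conditionMessage(e), call. = FALSE)

  ## -- input ----------------------------------------------------------
  if (is.null(unigenes)) {
    if (is.null(config$fasta)) stop("no input: supply fasta paths or unigenes")
    unigenes <- do.call(rbind, lapply(names(config$fasta), function(sp)
      read_fasta(config$fasta[[sp]], species = sp)))
  }
  if (is.null(annotation) && !is.null(config$annotation))
    annotation <- read_annotation(config$annotation)

  ## -- coding regions -------------------------------------------------
  coding <- tryCatch(
    resolve_coding_set(unigenes, hits, evalue_max = config$evalue_annotation,
                       min_len_nt = config$min_orf_nt),
    error = function(e) fail("coding_regions", e))
  stage("coding_regions", nrow(unigenes), nrow(coding),
        list(evalue_annotation = config$evalue_annotation,
             min_orf_nt = config$min_orf_nt))
  write_tsv(coding[, c("unigene_id", "species", "strand", "frame", "start",
                       "end", "source")],
            file.path(out, "coding_regions.tsv"))

  ## -- homology graph + families --------------------------------------
  proteins <- setNames(coding$protein, coding$unigene_id)
  edges <- tryCatch(
    homology_edges(proteins, evalue_max = config$evalue_homology),
    error = function(e) fail("homology_graph", e))
  clusters <- mcl_cluster(edges, genes = names(proteins))
  species_of <- setNames(coding$species, coding$unigene_id)
  families <- classify_families(clusters, species_of)
  stage("gene_families", length(proteins),
        length(unique(families$family_id)),
        list(evalue_homology = config$evalue_homology))
  write_tsv(edges, file.path(out, "edges.tsv"))
  write_tsv(as.data.frame(families), file.path(out, "families.tsv"))
  jsonlite::write_json(venn_counts(families),
                       file.path(out, "venn.json"),
                       dataframe = "columns", digits = NA, pretty = TRUE)

  ## -- single-copy ortholog Ka/Ks -------------------------------------
  fam_ids <- unique(families$family_id[families$copy_class ==
                                         "shared_single_copy"])
  cds_of <- setNames(coding$cds, coding$unigene_id)
  kaks_rows <- list()
  sc_alignments <- list()
  for (fid in fam_ids) {
    members <- families$gene_id[families$family_id == fid]
    prots <- setNames(coding$protein[match(members, coding$unigene_id)],
                      members)
    aln <- tryCatch(progressive_align(prots, type = "protein"),
                    error = function(e) fail("codon_evolution", e))
    prot_aln <- setNames(apply(aln, 1, paste, collapse = ""), rownames(aln))
    cod_aln <- back_translate(prot_aln, cds_of[members])
    sc_alignments[[fid]] <- cod_aln
    for (pr in combn(sort(members), 2, simplify = FALSE)) {
      st <- kaks_pair(cod_aln[pr])
      st$species_pair <- paste(sort(species_of[pr]), collapse = "-")
      st$family_id <- fid
      kaks_rows[[length(kaks_rows) + 1L]] <- st
    }
  }
  kaks <- if (length(kaks_rows)) do.call(rbind, kaks_rows) else NULL
  if (!is.null(kaks)) {
    kaks$selection_class <- classify_selection(kaks,
                                               ks_min = config$ks_min_ortholog)
    kaks$filtered <- kaks$selection_class == "excluded"
    stage("kaks_filter", nrow(kaks), sum(!kaks$filtered),
          list(ks_min = config$ks_min_ortholog))
    write_tsv(kaks, file.path(out, "kaks.tsv"))
  } else {
    stage("kaks_filter", 0L, 0L, list(ks_min = config$ks_min_ortholog))
  }

  ## -- enrichment of the positively selected set ----------------------
  enrichment <- NULL
  if (!is.null(annotation) && !is.null(kaks)) {
    pos <- kaks$selection_class %in% c("strong_positive", "weak_positive")
    query <- sort(unique(c(kaks$gene_a[pos], kaks$gene_b[pos])))
    background <- sort(names(proteins))
    if (length(query)) {
      enrichment <- enrich(query, annotation, background)
      write_tsv(enrichment, file.path(out, "enrichment.tsv"))
    }
    stage("enrichment", length(query),
          if (is.null(enrichment)) 0L else sum(enrichment$significant),
          list(alpha = 0.05))
  }

  ## -- supermatrix phylogeny ------------------------------------------
  tree <- NULL
  if (length(sc_alignments) >= 1L) {
    taxa <- sort(unique(coding$species))
    mats <- lapply(sc_alignments, function(cod_aln) {
      m <- do.call(rbind, strsplit(unname(cod_aln), ""))
      rownames(m) <- unname(species_of[names(cod_aln)])
      m[sort(rownames(m)), , drop = FALSE]
    })
    super <- concatenate_alignments(mats, taxa)
    if (length(taxa) >= 3L) {
      tree <- tryCatch(
        bootstrap_support(super$matrix, n_reps = config$n_bootstrap,
                          seed = stage_seed(config$seed, 5L)),
        error = function(e) fail("phylogeny", e))
      write_newick(tree, file.path(out, "tree.nwk"))
    }
    write_fasta(apply(super$matrix, 1, paste, collapse = ""),
                file.path(out, "supermatrix.fasta"))
    write_tsv(super$partitions, file.path(out, "partitions.tsv"))
    stage("phylogeny", length(sc_alignments), length(sc_alignments),
          list(n_bootstrap = config$n_bootstrap,
               supermatrix_width = ncol(super$matrix)))
  }

  ## -- paralog Ks dating ----------------------------------------------
  wgd <- list()
  ks_all <- list()
  for (sp in sort(unique(coding$species))) {
    cds_sp <- cds_of[coding$unigene_id[coding$species == sp]]
    pairs <- tryCatch(
      find_paralog_pairs(cds_sp, min_identity = config$min_identity,
                         min_aligned_nt = config$min_aligned_nt),
      error = function(e) fail("wgd_dating", e))
    ks_vals <- rep(NA_real_, nrow(pairs))
    for (r in seq_len(nrow(pairs))) {
      pa <- pairs$gene_a[r]; pb <- pairs$gene_b[r]
      prots <- setNames(c(translate_cds(cds_of[[pa]]),
                          translate_cds(cds_of[[pb]])), c(pa, pb))
      aln <- progressive_align(prots, type = "protein")
      prot_aln <- setNames(apply(aln, 1, paste, collapse = ""), rownames(aln))
      cod_aln <- back_translate(prot_aln, cds_of[c(pa, pb)])
      ks_vals[r] <- kaks_pair(cod_aln)$Ks
    }
    pairs$Ks <- ks_vals
    ks_kept <- ks_distribution(ks_vals, ks_max = config$ks_max_paralog)
    stage(paste0("ks_filter_", sp), length(ks_vals), length(ks_kept),
          list(ks_max = config$ks_max_paralog))
    ks_all[[sp]] <- ks_kept
    write_tsv(pairs, file.path(out, paste0("paralogs_", sp, ".tsv")))
  }
  ks_pool <- sort(unlist(ks_all, use.names = FALSE))
  if (length(ks_pool) >= 10 * config$mixture_k) {
    hist_df <- ks_histogram(ks_pool, bandwidth = config$bandwidth)
    write_tsv(hist_df, file.path(out, "ks_histogram.tsv"))
    fit <- em_fit(ks_pool, k = config$mixture_k,
                  seed = stage_seed(config$seed, 7L), rate = config$rate)
    wgd <- list(weights = fit$weights, mus = fit$mus, sigmas = fit$sigmas,
                loglik = fit$loglik, converged = fit$converged,
                ages_years = fit$ages_years, n = fit$n)
    jsonlite::write_json(wgd, file.path(out, "wgd_fit.json"),
                         digits = NA, pretty = TRUE, auto_unbox = FALSE)
    stage("wgd_fit", length(ks_pool), length(ks_pool),
          list(k = config$mixture_k, rate = config$rate))
  }

  report$families <- families
  report$venn <- venn_counts(families)
  report$kaks <- kaks
  report$tree <- tree
  report$enrichment <- enrichment
  report$wgd_fit <- wgd
  report$out_dir <- out
  ## serialized report: stage bookkeeping only (results live in artifacts)
  jsonlite::write_json(report$stages, file.path(out, "report.json"),
                       digits = NA, pretty = TRUE, auto_unbox = TRUE)
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("ploidtrace run report\n")
  for (s in x$stages) {
    cat(sprintf("  %-18s in %6d  out %6d  removed %6d\n",
                s$name, s$n_in, s$n_out, s$n_removed))
  }
  if (length(x$wgd_fit))
    cat("  WGD ages (My):",
        paste(round(x$wgd_fit$ages_years / 1e6, 2), collapse = ", "), "\n")
  invisible(x)
}
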