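## NG86 (Nei & Gojobori 1986) pathway-counting Ka/Ks estimation on
## protein-guided codon alignments, with the Fisher validity gate and the
## threshold-based selection classes used throughout the package.

#' Synonymous site fraction of a sense codon
#'
#' Sum over the three codon positions of the fraction of single-base
#' mutants that are synonymous, with mutations to stop codons excluded from
#' the denominator (NG86 convention). Values range from 0 (e.g. `ATG`) to
#' 1 at a fourfold-degenerate third position (e.g. `GGG`).
#'
#' @param codon a single sense codon (3-letter string over ACGT).
#' @return Synonymous site count in `[0, 3]`.
#' @examples
#' ng86_site_fraction("TTT")  # 1/3
#' ng86_site_fraction("GGG")  # 1
#' @export
ng86_site_fraction <- function(codon) {
  tabs <- genetic_code_tables()
  codon <- toupper(codon)
  if (!codon %in% tabs$sense) {
    stop("'", codon, "' is not a sense codon of the standard genetic code")
  }
  unname(tabs$syn_sites[codon])
}

#' Pathway-averaged synonymous/nonsynonymous differences between two codons
#'
#' Averages synonymous and nonsynonymous step counts over all minimal
#' mutational pathways between the codons. Pathways passing through a stop
#' codon are excluded; if every pathway does, all are kept (NG86 fallback).
#'
#' @param codon_a,codon_b sense codons.
#' @return Numeric vector `c(Sd, Nd)`.
#' @examples
#' ng86_differences("TTT", "TTC")  # c(1, 0)
#' ng86_differences("TTT", "GTA")  # c(0.5, 1.5)
#' @export
ng86_differences <- function(codon_a, codon_b) {
  tabs <- genetic_code_tables()
  codon_a <- toupper(codon_a); codon_b <- toupper(codon_b)
  for (cod in c(codon_a, codon_b)) {
    if (!cod %in% tabs$sense)
      stop("'", cod, "' is not a sense codon of the standard genetic code")
  }
  c(Sd = unname(tabs$sd[codon_a, codon_b]),
    Nd = unname(tabs$nd[codon_a, codon_b]))
}

#' Jukes-Cantor multiple-hit correction
#'
#' `d = -(3/4) log(1 - 4p/3)`. At or beyond the saturation boundary
#' (`p >= 3/4`) the distance is undefined and `NA` is returned rather than
#' an error, mirroring the "not applicable" flag carried through Ka/Ks
#' reporting.
#'
#' @param p observed proportion of differences, in `[0, 1]`.
#' @return Corrected distance, or `NA_real_` if saturated.
#' @export
jukes_cantor <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p must be in [0, 1]")
  out <- ifelse(p >= 0.75, NA_real_, -0.75 * log1p(-4 * p / 3))
  out
}

#' Back-translate a protein alignment onto its coding sequences
#'
#' Replaces each aligned residue by its source codon and each gap by a gap
#' codon (`---`), producing a codon alignment suitable for [kaks_pair()].
#'
#' @param prot_alignment named character vector of equal-length gapped
#'   amino-acid strings.
#' @param cds_map named list or character vector of ungapped CDS; each
#'   protein must translate exactly from its CDS.
#' @return Object of class `codon_alignment`: named character vector of
#'   gapped codon sequences with attribute `n_codons`.
#' @export
back_translate <- function(prot_alignment, cds_map) {
  if (is.null(names(prot_alignment)) || any(!nzchar(names(prot_alignment))))
    stop("prot_alignment must be named")
  widths <- unique(nchar(prot_alignment))
  if (length(widths) != 1L) stop("alignment rows differ in length")
  out <- character(length(prot_alignment))
  names(out) <- names(prot_alignment)
  for (id in names(prot_alignment)) {
    cds <- cds_map[[id]]
    if (is.null(cds)) stop("no CDS supplied for '", id, "'")
    codons <- split_codons(cds)
    ## drop a trailing stop codon if present
    if (codons[length(codons)] %in% .STOPS) codons <- codons[-length(codons)]
    prot <- translate_cds(paste(codons, collapse = ""))
    res <- strsplit(prot_alignment[[id]], "")[[1]]
    idx <- cumsum(res != "-")
    if (idx[length(idx)] != length(codons))
      stop("protein/CDS length mismatch for '", id, "'")
    aln_res <- res[res != "-"]
    mism <- which(aln_res != strsplit(prot, "")[[1]])
    if (length(mism))
      stop("protein/CDS mismatch for '", id, "' at residue ", mism[1])
    out[[id]] <- paste(ifelse(res == "-", "---", codons[idx]), collapse = "")
  }
  structure(out, n_codons = widths, class = "codon_alignment")
}

#' NG86 Ka/Ks statistics for one aligned coding-sequence pair
#'
#' Computes synonymous (S) and nonsynonymous (N) site counts averaged over
#' the two sequences, pathway-averaged difference counts (Sd, Nd) summed
#' over ungapped codon columns, Jukes-Cantor-corrected rates
#' `Ka = JC(Nd/N)` and `Ks = JC(Sd/S)`, the Ka/Ks ratio, and the Fisher
#' validity p-value. Columns containing a gap, an ambiguous base, or a stop
#' codon in either sequence are skipped.
#'
#' @param aln a `codon_alignment` (or character vector) of exactly two
#'   gapped codon sequences.
#' @return Object of class `ortholog_pair_stats`: a one-row data frame with
#'   columns `gene_a`, `gene_b`, `S`, `N`, `Sd`, `Nd`, `Ka`, `Ks`, `kaks`,
#'   `fisher_p`. `Ka`/`Ks` are `NA` when saturated; `kaks` is `NA` when
#'   either rate is `NA` or `Ks == 0`.
#' @export
kaks_pair <- function(aln) {
  if (length(aln) != 2L) stop("kaks_pair needs exactly two aligned sequences")
  tabs <- genetic_code_tables()
  ca <- split_codons(aln[[1]])
  cb <- split_codons(aln[[2]])
  if (length(ca) != length(cb)) stop("aligned sequences differ in length")
  usable <- ca %in% tabs$sense & cb %in% tabs$sense
  bad <- !usable & !(grepl("-", ca) | grepl("-", cb) |
                       grepl("N", ca) | grepl("N", cb))
  if (any(bad) && any(ca[bad] %in% .STOPS | cb[bad] %in% .STOPS))
    stop("alignment contains an internal stop codon")
  L <- sum(usable)
  if (L == 0L) stop("alignment has no comparable (ungapped, sense) codon columns")
  ia <- ca[usable]; ib <- cb[usable]
  S <- (sum(tabs$syn_sites[ia]) + sum(tabs$syn_sites[ib])) / 2
  N <- 3 * L - S
  idx <- cbind(match(ia, tabs$sense), match(ib, tabs$sense))
  Sd <- sum(tabs$sd[idx])
  Nd <- sum(tabs$nd[idx])
  Ka <- if (N > 0) jukes_cantor(Nd / N) else NA_real_
  Ks <- if (S > 0) jukes_cantor(Sd / S) else NA_real_
  kaks <- if (!is.na(Ka) && !is.na(Ks) && Ks > 0) Ka / Ks else NA_real_
  p <- fisher_gate(S, N, Sd, Nd)
  ids <- names(aln)
  if (is.null(ids)) ids <- c("seq_a", "seq_b")
  structure(
    data.frame(gene_a = ids[1], gene_b = ids[2], S = S, N = N, Sd = Sd,
               Nd = Nd, Ka = Ka, Ks = Ks, kaks = kaks, fisher_p = p,
               stringsAsFactors = FALSE),
    class = c("ortholog_pair_stats", "data.frame"))
}

#' Fisher's exact validity test for an NG86 site/difference table
#'
#' Two-sided Fisher's exact test on the 2x2 table
#' `[[Sd, S - Sd], [Nd, N - Nd]]`. Fractional pathway-averaged counts are
#' rounded half-up to integers, the convention fixed for determinism.
#'
#' @param S,N synonymous / nonsynonymous site counts (positive).
#' @param Sd,Nd synonymous / nonsynonymous difference counts.
#' @return Two-sided p-value.
#' @export
fisher_gate <- function(S, N, Sd, Nd) {
  if (any(c(S, N, Sd, Nd) < 0)) stop("site and difference counts must be >= 0")
  r <- function(x) floor(x + 0.5)  # round half-up
  S <- r(S); N <- r(N); Sd <- min(r(Sd), S); Nd <- min(r(Nd), N)
  tab <- matrix(c(Sd, S - Sd, Nd, N - Nd), nrow = 2, byrow = TRUE)
  stats::fisher.test(tab)$p.value
}

#' Classify a Ka/Ks pair into selection classes
#'
#' Pairs with `Ks <= ks_min` (potential paralogs) or a non-applicable Ka or
#' Ks are `excluded`. Remaining pairs are binned: `strong_positive`
#' (Ka/Ks > 1), `weak_positive` (0.5 < Ka/Ks <= 1), `neutral`
#' (0.1 <= Ka/Ks <= 0.5), `purifying` (Ka/Ks < 0.1). A `Ka = 0` pair has
#' ratio 0 and is kept as `purifying`.
#'
#' @param stats an `ortholog_pair_stats` row (or data frame of them).
#' @param ks_min Ks filter threshold retained pairs must exceed
#'   (default 0.1).
#' @return Character vector of classes, one per row.
#' @export
classify_selection <- function(stats, ks_min = 0.1) {
  ks <- stats$Ks
  ka <- stats$Ka
  ratio <- stats$kaks
  ratio[!is.na(ka) & ka == 0 & !is.na(ks) & ks > 0] <- 0
  out <- rep("excluded", length(ks))
  ok <- !is.na(ka) & !is.na(ks) & ks > ks_min & !is.na(ratio)
  out[ok & ratio > 1] <- "strong_positive"
  out[ok & ratio > 0.5 & ratio <= 1] <- "weak_positive"
  out[ok & ratio >= 0.1 & ratio <= 0.5] <- "neutral"
  out[ok & ratio < 0.1] <- "purifying"
  out
}

#' @export
print.ortholog_pair_stats <- function(x, ...) {
  cat("NG86 Ka/Ks pair statistics\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
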