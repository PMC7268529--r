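## Genetic-code lookup tables used by the NG86 estimator and the mutation
## generator.  Built once per session from the standard code shipped with
## Biostrings and cached.

.BASES <- c("A", "C", "G", "T")
.STOPS <- c("TAA", "TAG", "TGA")

#' Standard genetic code tables for NG86 computations
#'
#' Builds (and caches) lookup tables over the 61 sense codons:
#' per-position synonymous site fractions, the NG86 pathway-averaged
#' (Sd, Nd) matrix over all sense-codon pairs, and per-position mutation
#' target sets used by the sequence generator.
#'
#' @return A list with elements `sense` (codon names), `aa` (amino acid per
#'   sense codon), `site` (61 x 3 matrix of synonymous site fractions),
#'   `syn_sites` (numeric vector, total synonymous sites per codon),
#'   `sd` and `nd` (61 x 61 pathway-averaged difference matrices), and
#'   `mut` (nested list: `mut[[codon]][[pos]]$syn` / `$nonsyn`, replacement
#'   bases yielding non-stop synonymous / nonsynonymous mutants).
#' @keywords internal
#' @noRd
genetic_code_tables <- function() {
  if (!is.null(.ploidtrace_cache$ng86)) return(.ploidtrace_cache$ng86)
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  aa <- code[sense]

  ## per-position synonymous site fractions, stop mutants excluded from the
  ## denominator (NG86 convention)
  site <- matrix(0, length(sense), 3, dimnames = list(sense, NULL))
  mut <- vector("list", length(sense))
  names(mut) <- sense
  for (cod in sense) {
    letters3 <- strsplit(cod, "")[[1]]
    mut[[cod]] <- vector("list", 3)
    for (pos in 1:3) {
      alt <- setdiff(.BASES, letters3[pos])
      mutants <- vapply(alt, function(b) {
        m <- letters3; m[pos] <- b; paste(m, collapse = "")
      }, character(1))
      keep <- !(mutants %in% .STOPS)
      syn <- keep & code[mutants] == code[cod]
      denom <- sum(keep)
      site[cod, pos] <- if (denom > 0) sum(syn) / denom else 0
      mut[[cod]][[pos]] <- list(
        syn    = alt[syn],
        nonsyn = alt[keep & !syn]
      )
    }
  }

  ## pathway-averaged differences for every sense-codon pair
  n <- length(sense)
  sd_mat <- matrix(0, n, n, dimnames = list(sense, sense))
  nd_mat <- matrix(0, n, n, dimnames = list(sense, sense))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) next
      cnt <- ng86_path_counts(sense[i], sense[j], code)
      sd_mat[i, j] <- sd_mat[j, i] <- cnt[1]
      nd_mat[i, j] <- nd_mat[j, i] <- cnt[2]
    }
  }

  tabs <- list(sense = sense, aa = aa, site = site,
               syn_sites = rowSums(site), sd = sd_mat, nd = nd_mat,
               mut = mut)
  .ploidtrace_cache$ng86 <- tabs
  tabs
}

## Pathway-averaged (Sd, Nd) between two sense codons: average synonymous /
## nonsynonymous step counts over all orderings of the differing positions,
## excluding pathways through stop codons (falling back to all pathways if
## every ordering passes through a stop).
ng86_path_counts <- function(a, b, code = Biostrings::GENETIC_CODE) {
  la <- strsplit(a, "")[[1]]
  lb <- strsplit(b, "")[[1]]
  diffs <- which(la != lb)
  k <- length(diffs)
  if (k == 0L) return(c(0, 0))
  perms <- permutations_of(diffs)
  res <- matrix(NA_real_, nrow = length(perms), ncol = 2)
  valid <- logical(length(perms))
  for (p in seq_along(perms)) {
    cur <- la
    s <- 0; ns <- 0; ok <- TRUE
    for (step in seq_len(k)) {
      pos <- perms[[p]][step]
      prev <- paste(cur, collapse = "")
      cur[pos] <- lb[pos]
      nxt <- paste(cur, collapse = "")
      if (step < k && nxt %in% .STOPS) ok <- FALSE
      if (code[[prev]] == code[[nxt]] ||
          (nxt %in% .STOPS && prev %in% .STOPS)) {
        s <- s + 1
      } else if (nxt %in% .STOPS || prev %in% .STOPS) {
        ## step into/out of a stop on a fallback pathway: classify by the
        ## amino-acid change being non-silent
        ns <- ns + 1
      } else {
        ns <- ns + 1
      }
    }
    res[p, ] <- c(s, ns)
    valid[p] <- ok
  }
  use <- if (any(valid)) valid else rep(TRUE, length(perms))
  colMeans(res[use, , drop = FALSE])
}

## all orderings of a short vector (k <= 3 here)
permutations_of <- function(x) {
  k <- length(x)
  if (k == 1L) return(list(x))
  out <- list()
  for (i in seq_len(k)) {
    for (rest in permutations_of(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

#' Split a CDS string into codons
#' @keywords internal
#' @noRd
split_codons <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("sequence length ", n, " is not divisible by 3")
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}
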