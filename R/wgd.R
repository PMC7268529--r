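## Whole-genome-duplication dating: within-species paralog detection,
## Ks age distribution, EM Gaussian-mixture peak fitting, and age
## conversion T = Ks / (2 r).

#' Detect within-species paralog pairs by nucleotide similarity
#'
#' All intra-species coding-sequence pairs whose best local alignment
#' (match 2 / mismatch -3, gap open 5, extend 1) reaches at least
#' `min_identity` identity over at least `min_aligned_nt` aligned
#' nucleotides. Candidate pairs are prefiltered by shared 11-mers.
#'
#' @param cds_set named character vector of coding sequences from one
#'   species.
#' @param min_identity identity threshold (default 0.40).
#' @param min_aligned_nt minimum alignment length in nt (default 300).
#' @return Data frame (`gene_a`, `gene_b`, `identity`, `aligned_nt`), each
#'   unordered pair once, canonical order.
#' @export
find_paralog_pairs <- function(cds_set, min_identity = 0.40,
                               min_aligned_nt = 300) {
  stopifnot(!is.null(names(cds_set)))
  if (length(cds_set) < 2L)
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      identity = numeric(0), aligned_nt = integer(0)))
  cand <- kmer_candidate_pairs(cds_set, k = 11L, min_shared = 2L)
  submat <- msa_submat("dna")
  ids <- names(cds_set)
  rows <- vector("list", nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(cds_set[[i]]), Biostrings::DNAString(cds_set[[j]]),
      type = "local", substitutionMatrix = submat,
      gapOpening = 5, gapExtension = 2)
    alen <- nchar(as.character(Biostrings::alignedPattern(aln)))
    ident <- if (alen > 0) Biostrings::nmatch(aln) / alen else 0
    if (alen >= min_aligned_nt && ident >= min_identity) {
      o <- order(c(ids[i], ids[j]))
      ab <- c(ids[i], ids[j])[o]
      rows[[r]] <- data.frame(gene_a = ab[1], gene_b = ab[2],
                              identity = ident, aligned_nt = alen,
                              stringsAsFactors = FALSE)
    }
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      identity = numeric(0), aligned_nt = integer(0)))
  out <- do.call(rbind, rows)
  out[order(out$gene_a, out$gene_b), , drop = FALSE]
}

#' Filter paralog Ks values for age-distribution analysis
#'
#' Retains applicable Ks values with `0 < Ks <= ks_max`; saturated (`NA`)
#' values and Ks beyond the saturation cap are dropped.
#'
#' @param ks numeric vector of Ks values (may contain `NA`).
#' @param ks_max saturation cap (default 2).
#' @return Filtered numeric vector.
#' @export
ks_distribution <- function(ks, ks_max = 2) {
  ks[!is.na(ks) & ks > 0 & ks <= ks_max]
}

#' Fixed-bandwidth histogram of a Ks age distribution
#'
#' Bins of width `bandwidth` starting at 0 and covering `(0, 2]`; with the
#' default 0.03 this gives 67 bins, the last right-closed. Counts sum to
#' the input size.
#'
#' @param ks numeric vector of Ks values in `(0, 2]` (pre-filtered with
#'   [ks_distribution()]).
#' @param bandwidth bin width (default 0.03).
#' @return Data frame (`bin_start`, `bin_end`, `count`).
#' @export
ks_histogram <- function(ks, bandwidth = 0.03) {
  if (!length(ks)) stop("empty Ks vector")
  if (any(ks <= 0 | ks > 2))
    stop("Ks values outside (0, 2]; filter with ks_distribution() first")
  n_bins <- ceiling(2 / bandwidth)
  breaks <- bandwidth * seq(0, n_bins)
  idx <- pmin(findInterval(ks, breaks, left.open = FALSE), n_bins)
  ## left-closed bins [b, b+w), except values exactly on a break fall in the
  ## upper bin by findInterval; the final bin is right-closed via pmin
  data.frame(bin_start = breaks[-length(breaks)],
             bin_end = breaks[-1],
             count = tabulate(idx, nbins = n_bins))
}

#' Fit a univariate Gaussian mixture to Ks values by EM
#'
#' Standard EM for a k-component univariate normal mixture on the raw Ks
#' axis (no truncation correction, matching common Ks-peak practice).
#' Initialization places component means at evenly spaced sample quantiles
#' with the pooled standard deviation; the best of `n_restarts` seeded
#' restarts (quantile means jittered after the first) by log-likelihood is
#' returned. The log-likelihood is non-decreasing across iterations.
#'
#' @param ks numeric vector, `length(ks) >= 10 * k`.
#' @param k number of components (default 3).
#' @param seed integer seed controlling restart jitter.
#' @param tol stop when the log-likelihood improves by less than this
#'   (default `1e-6`).
#' @param max_iter iteration cap per restart (default 500).
#' @param n_restarts number of seeded restarts (default 5).
#' @param rate substitutions/site/year used for `ages_years` (default
#'   `6.1e-9`).
#' @return Object of class `ks_mixture_fit`: list with `k`, `weights`,
#'   `mus` (ascending), `sigmas`, `loglik`, `loglik_trace`, `n_iter`,
#'   `converged`, `ages_years = mus / (2 * rate)`, `n`.
#' @export
em_fit <- function(ks, k = 3, seed = 1, tol = 1e-6, max_iter = 500,
                   n_restarts = 5, rate = 6.1e-9) {
  x <- as.numeric(ks)
  n <- length(x)
  if (n < 10 * k) stop("need at least ", 10 * k, " values to fit ", k,
                       " components")
  best <- NULL
  with_rng_seed(seed, {
    for (r in seq_len(n_restarts)) {
      mu <- as.numeric(quantile(x, probs = (2 * seq_len(k) - 1) / (2 * k)))
      if (r > 1) mu <- mu + rnorm(k, 0, sd(x) / 4)
      fit <- em_once(x, k, mu, tol, max_iter)
      if (is.null(fit)) next
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
  })
  if (is.null(best))
    stop("all EM restarts collapsed (a component variance degenerated)")
  ord <- order(best$mus)
  structure(list(k = k, weights = best$weights[ord], mus = best$mus[ord],
                 sigmas = best$sigmas[ord], loglik = best$loglik,
                 loglik_trace = best$trace, n_iter = best$n_iter,
                 converged = best$converged,
                 ages_years = age_from_ks(best$mus[ord], rate), n = n),
            class = "ks_mixture_fit")
}

em_once <- function(x, k, mu, tol, max_iter) {
  n <- length(x)
  sigma <- rep(sd(x), k)
  w <- rep(1 / k, k)
  ll_prev <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j) w[j] * dnorm(x, mu[j], sigma[j]),
                   numeric(n))
    rowsum_d <- rowSums(dens)
    rowsum_d[rowsum_d == 0] <- .Machine$double.xmin
    ll <- sum(log(rowsum_d))
    trace <- c(trace, ll)
    if (ll - ll_prev < tol && it > 1) { converged <- TRUE; break }
    ll_prev <- ll
    resp <- dens / rowsum_d
    nk <- colSums(resp)
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sigma <- sqrt(colSums(resp * (outer(x, mu, "-"))^2) / nk)
    if (any(!is.finite(sigma)) || any(sigma < 1e-4)) return(NULL)
  }
  list(weights = w, mus = mu, sigmas = sigma, loglik = trace[length(trace)],
       trace = trace, n_iter = length(trace), converged = converged)
}

#' Convert a modal Ks value to a duplication age
#'
#' `T = Ks / (2 r)` with `r` the per-site synonymous substitution rate per
#' year (default `6.1e-9`, a plant-average rate).
#'
#' @param ks_mode modal Ks value(s), >= 0.
#' @param rate substitution rate per site per year, > 0.
#' @return Age(s) in years. Linear in `ks_mode`.
#' @examples
#' age_from_ks(0.11) / 1e6  # ~9.02 million years
#' @export
age_from_ks <- function(ks_mode, rate = 6.1e-9) {
  if (rate <= 0) stop("rate must be > 0")
  if (any(ks_mode < 0)) stop("ks_mode must be >= 0")
  ks_mode / (2 * rate)
}

#' @export
print.ks_mixture_fit <- function(x, ...) {
  cat(sprintf("Gaussian mixture fit on %d Ks values (k = %d, loglik %.2f)\n",
              x$n, x$k, x$loglik))
  print(data.frame(weight = round(x$weights, 4), mu = round(x$mus, 4),
                   sigma = round(x$sigmas, 4),
                   age_My = round(x$ages_years / 1e6, 2)))
  invisible(x)
}
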