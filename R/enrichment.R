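## Hypergeometric over-representation test with Bonferroni correction.

#' Upper-tail hypergeometric probability
#'
#' Evaluates `P = 1 - sum_{i=0}^{m-1} C(M,i) C(N-M,n-i) / C(N,n)`, the
#' probability of observing `m` or more annotated genes in a sample of `n`
#' from a background of `N` genes of which `M` carry the term. Computed as
#' the upper-tail sum in log-space for numerical stability with large
#' binomial coefficients.
#'
#' @param N background size (annotated genes).
#' @param M background genes carrying the term.
#' @param n query size.
#' @param m query genes carrying the term.
#' @return The probability `P(X >= m)`.
#' @examples
#' hypergeom_tail(10, 5, 4, 4)  # 1/42
#' @export
hypergeom_tail <- function(N, M, n, m) {
  if (any(c(N, M, n, m) < 0) || M > N || n > N || m > min(n, M))
    stop("require 0 <= M <= N, 0 <= n <= N, 0 <= m <= min(n, M)")
  if (m == 0) return(1)
  i <- m:min(n, M)
  lo <- max(0, n - (N - M))
  i <- i[i >= lo]
  sum(exp(lchoose(M, i) + lchoose(N - M, n - i) - lchoose(N, n)))
}

#' Term over-representation in a query gene set
#'
#' For every annotation term observed at least once in the query (`m >= 1`),
#' tests over-representation with [hypergeom_tail()] against the annotated
#' background, applies Bonferroni correction with the number of tested
#' terms as the factor, and flags terms with corrected p below `alpha`.
#' Following the standard glossary: `N` = annotated genes in the
#' background, `M` = background genes with the term, `n` = annotated query
#' genes, `m` = query genes with the term.
#'
#' @param query character vector of query gene ids (must be a subset of
#'   `background`).
#' @param annotation data frame with columns `gene_id`, `term_id` (an
#'   optional `ontology` column is carried through).
#' @param background character vector of background gene ids.
#' @param alpha significance level on the corrected p (default 0.05).
#' @return Data frame (`term_id`, `N`, `M`, `n`, `m`, `p`, `p_bonf`,
#'   `significant`, `n_tested`) ordered by `p` then `term_id`.
#' @export
enrich <- function(query, annotation, background, alpha = 0.05) {
  missing_q <- setdiff(query, background)
  if (length(missing_q))
    stop("query gene absent from background: ", missing_q[1])
  ann <- annotation[annotation$gene_id %in% background, , drop = FALSE]
  annotated <- unique(ann$gene_id)
  N <- length(annotated)
  q_ann <- intersect(query, annotated)
  n <- length(q_ann)
  terms <- sort(unique(ann$term_id[ann$gene_id %in% q_ann]))
  if (!length(terms))
    return(data.frame(term_id = character(0), N = integer(0), M = integer(0),
                      n = integer(0), m = integer(0), p = numeric(0),
                      p_bonf = numeric(0), significant = logical(0),
                      n_tested = integer(0)))
  by_term <- split(ann$gene_id, ann$term_id)
  M <- vapply(terms, function(t) length(unique(by_term[[t]])), 0L)
  m <- vapply(terms, function(t) length(intersect(by_term[[t]], q_ann)), 0L)
  p <- mapply(hypergeom_tail, N = N, M = M, n = n, m = m)
  k <- length(terms)
  p_bonf <- pmin(1, p * k)
  out <- data.frame(term_id = terms, N = N, M = M, n = n, m = m, p = p,
                    p_bonf = p_bonf, significant = p_bonf < alpha,
                    n_tested = k, row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$p, out$term_id), , drop = FALSE]
}
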