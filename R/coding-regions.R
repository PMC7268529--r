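## Identification of the protein-coding region of each unigene: an
## annotation-guided route (precomputed hit tables with a database priority
## rule) and a deterministic six-frame longest-ORF fallback.

#' Translate a coding sequence with the standard genetic code
#'
#' A single trailing stop codon is dropped; an internal stop is an error.
#' Codons containing `N` translate to `X` (and `X` never counts as a stop).
#'
#' @param cds nucleotide string over ACGTN, length divisible by 3.
#' @return Amino-acid string.
#' @examples
#' translate_cds("ATGTTTTAA")  # "MF"
#' @export
translate_cds <- function(cds) {
  cds <- toupper(cds)
  check_nucleotides(cds)
  codons <- split_codons(cds)
  code <- Biostrings::GENETIC_CODE
  aa <- ifelse(grepl("N", codons), "X",
               unname(code[codons]))
  if (anyNA(aa)) stop("untranslatable codon at position ", which(is.na(aa))[1])
  n <- length(aa)
  if (aa[n] == "*") aa <- aa[-n]
  if (any(aa == "*"))
    stop("internal stop codon at codon ", which(aa == "*")[1])
  paste(aa, collapse = "")
}

check_nucleotides <- function(seq) {
  bad <- regexpr("[^ACGTN]", seq)
  if (bad > 0)
    stop("invalid nucleotide '", substr(seq, bad, bad), "' at position ", bad)
  invisible(TRUE)
}

#' Reverse complement of a nucleotide string
#' @param seq nucleotide string over ACGTN.
#' @return Reverse-complemented string.
#' @export
reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Find the longest open reading frame across all six frames
#'
#' Scans both strands and all three frames for ORFs (ATG through the last
#' sense codon before a stop, or through the sequence end) and returns the
#' longest with length `>= min_len_nt`. Ties are broken deterministically:
#' prefer the `+` strand, then the lower frame index, then the smaller
#' forward-strand start. Coordinates are 0-based half-open on the forward
#' strand and exclude the stop codon.
#'
#' @param unigene a list/one-row data frame with fields `id` and `seq`, or a
#'   plain nucleotide string.
#' @param min_len_nt minimum ORF length in nucleotides (default 150).
#' @return A `coding_region` (list with `unigene_id`, `strand`, `frame`,
#'   `start`, `end`, `cds`, `protein`, `source = "orf_heuristic"`), or
#'   `NULL` if no qualifying ORF exists.
#' @export
find_coding_region <- function(unigene, min_len_nt = 150) {
  if (is.character(unigene)) unigene <- list(id = "unigene", seq = unigene)
  seq <- toupper(unigene$seq)
  if (!nzchar(seq)) stop("empty sequence")
  check_nucleotides(seq)
  L <- nchar(seq)
  cand <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else reverse_complement(seq)
    for (frame in 0:2) {
      n_cod <- (nchar(s) - frame) %/% 3L
      if (n_cod < 1L) next
      starts <- frame + seq(0L, by = 3L, length.out = n_cod) + 1L
      codons <- substring(s, starts, starts + 2L)
      is_stop <- codons %in% .STOPS
      is_atg <- codons == "ATG"
      ## segment index between stops; ORF = first ATG in segment .. segment end
      seg <- cumsum(c(TRUE, is_stop[-n_cod]))
      for (g in split(seq_len(n_cod), seg)) {
        g <- g[!is_stop[g]]
        if (!length(g)) next
        a <- g[is_atg[g]]
        if (!length(a)) next
        first <- a[1]
        len <- (g[length(g)] - first + 1L) * 3L
        if (len < min_len_nt) next
        s_start <- starts[first] - 1L           # 0-based on scanned strand
        s_end <- s_start + len
        if (strand == "+") {
          fstart <- s_start; fend <- s_end
        } else {
          fstart <- L - s_end; fend <- L - s_start
        }
        cand[[length(cand) + 1L]] <- list(
          strand = strand, frame = frame, start = fstart, end = fend,
          len = len, cds = substr(s, s_start + 1L, s_end))
      }
    }
  }
  if (!length(cand)) return(NULL)
  ord <- order(-vapply(cand, `[[`, 0L, "len"),
               vapply(cand, `[[`, "", "strand") != "+",
               vapply(cand, `[[`, 0L, "frame"),
               vapply(cand, `[[`, 0L, "start"))
  best <- cand[[ord[1]]]
  new_coding_region(unigene$id, best$strand, best$frame, best$start,
                    best$end, best$cds, "orf_heuristic")
}

new_coding_region <- function(id, strand, frame, start, end, cds, source) {
  structure(list(unigene_id = id, strand = strand, frame = frame,
                 start = start, end = end, cds = cds,
                 protein = translate_cds(cds), source = source),
            class = "coding_region")
}

#' @export
print.coding_region <- function(x, ...) {
  cat(sprintf("coding_region %s [%d,%d) strand %s frame %d (%s), %d aa\n",
              x$unigene_id, x$start, x$end, x$strand, x$frame, x$source,
              nchar(x$protein)))
  invisible(x)
}

.DB_PRIORITY <- c("Nr", "SwissProt", "KEGG", "COG")

#' Resolve the coding region of a unigene from hits or the ORF heuristic
#'
#' If a hit table is supplied, hits with `evalue < evalue_max` are ranked by
#' database priority (Nr > Swiss-Prot > KEGG > COG) and then by smallest
#' e-value; the best hit's strand/frame and aligned interval determine the
#' coding region (trimmed to codon boundaries and at the first stop).
#' Otherwise (or with no qualifying hit) the six-frame ORF heuristic is
#' used. Unigenes with neither are dropped (`NULL`).
#'
#' @param unigene list with `id` and `seq`.
#' @param hits optional data frame with columns `unigene_id`, `database`,
#'   `evalue`, `strand`, `frame`, `start`, `end` (0-based half-open,
#'   forward strand).
#' @param evalue_max annotation e-value cutoff (default `1e-5`).
#' @param min_len_nt minimum ORF length for the fallback.
#' @return A `coding_region` or `NULL`.
#' @export
resolve_coding <- function(unigene, hits = NULL, evalue_max = 1e-5,
                           min_len_nt = 150) {
  if (!is.null(hits) && nrow(hits)) {
    h <- hits[hits$unigene_id == unigene$id & hits$evalue < evalue_max, ,
              drop = FALSE]
    if (nrow(h)) {
      pri <- match(h$database, .DB_PRIORITY)
      if (anyNA(pri)) stop("unknown database: ", h$database[is.na(pri)][1])
      h <- h[order(pri, h$evalue), , drop = FALSE]
      best <- h[1, ]
      return(region_from_hit(unigene, best))
    }
  }
  find_coding_region(unigene, min_len_nt = min_len_nt)
}

## Build a coding region from a hit's strand/frame and aligned interval:
## snap the interval to the hit frame's codon grid, trim to a whole number
## of codons, and truncate at the first in-frame stop.
region_from_hit <- function(unigene, hit) {
  seq <- toupper(unigene$seq)
  L <- nchar(seq)
  s <- if (hit$strand == "+") seq else reverse_complement(seq)
  ## interval on the scanned strand
  if (hit$strand == "+") {
    a <- hit$start; b <- hit$end
  } else {
    a <- L - hit$end; b <- L - hit$start
  }
  a <- a + ((hit$frame - a) %% 3L)      # snap start onto the frame grid
  b <- a + ((b - a) %/% 3L) * 3L
  if (b <= a) return(NULL)
  codons <- split_codons(substr(s, a + 1L, b))
  stop_at <- which(codons %in% .STOPS)
  if (length(stop_at)) codons <- codons[seq_len(stop_at[1] - 1L)]
  if (!length(codons)) return(NULL)
  b <- a + 3L * length(codons)
  if (hit$strand == "+") {
    fstart <- a; fend <- b
  } else {
    fstart <- L - b; fend <- L - a
  }
  new_coding_region(unigene$id, hit$strand, hit$frame, fstart, fend,
                    paste(codons, collapse = ""), "annotation")
}

#' Resolve coding regions for a set of unigenes
#'
#' Vectorized driver over [resolve_coding()]; hit-table rows referencing an
#' unknown unigene id are an error.
#'
#' @param unigenes data frame with columns `id`, `species`, `seq`.
#' @param hits optional hit table (see [resolve_coding()]).
#' @param evalue_max,min_len_nt passed through.
#' @return Data frame with one row per unigene that has a coding region:
#'   `unigene_id`, `species`, `strand`, `frame`, `start`, `end`, `source`,
#'   `cds`, `protein`.
#' @export
resolve_coding_set <- function(unigenes, hits = NULL, evalue_max = 1e-5,
                               min_len_nt = 150) {
  if (!is.null(hits) && nrow(hits)) {
    unknown <- setdiff(unique(hits$unigene_id), unigenes$id)
    if (length(unknown))
      stop("hit table references unknown unigene id: ", unknown[1])
  }
  rows <- vector("list", nrow(unigenes))
  for (i in seq_len(nrow(unigenes))) {
    u <- list(id = unigenes$id[i], seq = unigenes$seq[i])
    h <- if (is.null(hits)) NULL else
      hits[hits$unigene_id == u$id, , drop = FALSE]
    cr <- resolve_coding(u, h, evalue_max = evalue_max,
                         min_len_nt = min_len_nt)
    if (is.null(cr)) next
    rows[[i]] <- data.frame(
      unigene_id = cr$unigene_id, species = unigenes$species[i],
      strand = cr$strand, frame = cr$frame, start = cr$start, end = cr$end,
      source = cr$source, cds = cr$cds, protein = cr$protein,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
}
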