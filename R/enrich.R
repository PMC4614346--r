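# Hypergeometric enrichment of candidate gene sets over a flat
# gene-to-term map, with Bonferroni (GO) or Benjamini-Hochberg FDR
# (KEGG) control.  Only terms with at least one candidate gene are
# tested; the multiple-testing denominator counts exactly those.

#' Upper-tail hypergeometric probability
#'
#' \eqn{P(X \ge m)} for X hypergeometric: a candidate set of n genes
#' drawn from a universe of N genes of which M carry the term.  The sum
#' \eqn{\sum_{k \ge m} C(M,k) C(N-M,n-k) / C(N,n)} is accumulated in
#' log space.
#'
#' @param N universe size (genes with annotation).
#' @param n candidate-set size within the universe.
#' @param M genes annotated to the term.
#' @param m candidate genes annotated to the term.
#' @return p-value in (0, 1].
#' @export
hypergeom_tail <- function(N, n, M, m) {
  if (any(c(N, n, M, m) < 0) || n > N || M > N)
    stop("invalid hypergeometric configuration")
  if (m > min(n, M))
    stop("impossible configuration: m exceeds min(n, M)")
  if (m == 0) return(1)
  k <- m:min(n, M)
  lt <- lchoose(M, k) + lchoose(N - M, n - k) - lchoose(N, n)
  p <- exp(.logsumexp(lt))
  min(max(p, 0), 1)
}

#' Term enrichment of a candidate gene set
#'
#' @param candidates character vector of candidate gene ids; genes
#'   outside the annotation universe are dropped (their number is
#'   reported in the \code{dropped} attribute).
#' @param gene2term data.frame with columns \code{gene} and \code{term}
#'   (a gene may carry several terms).
#' @param method multiple-testing correction: \code{"bonferroni"} or
#'   \code{"bh_fdr"}.
#' @param alpha significance threshold on the adjusted p-value.
#' @return data.frame of class \code{enrichment_table}, one row per term
#'   with at least one candidate gene: \code{term}, \code{N}, \code{n},
#'   \code{M}, \code{m}, \code{p_raw}, \code{p_adjusted},
#'   \code{enriched}; sorted by raw p-value.
#' @export
enrich_terms <- function(candidates, gene2term,
                         method = c("bonferroni", "bh_fdr"),
                         alpha = 0.05) {
  method <- match.arg(method)
  stopifnot(all(c("gene", "term") %in% names(gene2term)))
  if (nrow(gene2term) == 0L) stop("empty gene-to-term map")
  universe <- unique(gene2term$gene)
  candidates <- unique(candidates)
  dropped <- sum(!candidates %in% universe)
  cand <- intersect(candidates, universe)
  N <- length(universe)
  n <- length(cand)
  empty <- structure(
    data.frame(term = character(0), N = integer(0), n = integer(0),
               M = integer(0), m = integer(0), p_raw = numeric(0),
               p_adjusted = numeric(0), enriched = logical(0),
               stringsAsFactors = FALSE),
    class = c("enrichment_table", "data.frame"), dropped = dropped)
  if (n == 0L) return(empty)
  bycand <- gene2term[gene2term$gene %in% cand, ]
  terms <- sort(unique(bycand$term), method = "radix")
  if (!length(terms)) return(empty)
  M <- vapply(terms, function(t)
    length(unique(gene2term$gene[gene2term$term == t])), 0L)
  m <- vapply(terms, function(t)
    length(unique(bycand$gene[bycand$term == t])), 0L)
  p_raw <- vapply(seq_along(terms),
                  function(i) hypergeom_tail(N, n, M[i], m[i]), 0)
  p_adj <- switch(method,
                  bonferroni = pmin(1, p_raw * length(terms)),
                  bh_fdr = p.adjust(p_raw, method = "BH"))
  out <- data.frame(term = terms, N = N, n = n, M = M, m = m,
                    p_raw = p_raw, p_adjusted = p_adj,
                    enriched = p_adj <= alpha,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_raw, out$term, method = "radix"), ]
  rownames(out) <- NULL
  structure(out, class = c("enrichment_table", "data.frame"),
            dropped = dropped)
}
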