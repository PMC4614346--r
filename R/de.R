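# Normalization, replicate QC, fold-change and the count-based
# significance test.
#
# Counts are normalized to tags-per-million of library clean reads;
# exact zeros are replaced by 0.01 so fold-changes stay defined.
# Replicates of one strain are pooled (counts and clean-read totals
# summed) before normalization and testing.  Significance uses the
# Audic-Claverie two-library statistic: conditional on x tags in a
# library of N1 clean reads, the count y in a library of N2 clean reads
# follows, under equal underlying abundance, the distribution
#   p(y | x) = r^y (x+y)! / (x! y! (1+r)^(x+y+1)),   r = N2/N1,
# and the reported p-value is the doubled smaller tail (capped at 1).

#' Normalize a tag count to tags-per-million
#'
#' @param count non-negative integer count(s).
#' @param total positive total clean-read count of the library.
#' @param zero_sub replacement applied to exact zeros (default 0.01).
#' @return numeric normalized expression, \code{count / total * 1e6},
#'   with zeros replaced by \code{zero_sub}.
#' @export
normalize_expression <- function(count, total, zero_sub = 0.01) {
  if (any(total <= 0)) stop("library total must be positive")
  if (any(count < 0)) stop("counts must be non-negative")
  v <- count / total * 1e6
  v[v == 0] <- zero_sub
  v
}

#' Log2 fold-change of normalized expressions
#'
#' @param norm_treated,norm_control positive normalized expressions.
#' @return \code{log2(norm_treated / norm_control)}.
#' @export
fold_change <- function(norm_treated, norm_control) {
  if (any(norm_treated <= 0) || any(norm_control <= 0))
    stop("normalized expressions must be positive (apply the zero ",
         "substitution first)")
  log2(norm_treated / norm_control)
}

# log(sum(exp(x))) computed stably
.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log p(k | x) for the Audic-Claverie conditional distribution
.ac_log_term <- function(k, x, logr, log1pr) {
  k * logr + lgamma(x + k + 1) - lgamma(x + 1) - lgamma(k + 1) -
    (x + k + 1) * log1pr
}

#' Count-based two-library p-value (Audic-Claverie style)
#'
#' Two-sided tail probability for observing counts \code{x} and \code{y}
#' of one tag in libraries of size \code{N1} and \code{N2}: twice the
#' smaller of the two conditional tails \eqn{P(Y \le y | x)} and
#' \eqn{P(Y \ge y | x)}, capped at 1.  Both tails are summed directly in
#' log space (the upper tail by truncated summation), so very small
#' p-values keep full relative precision.
#'
#' @param x,y non-negative integer counts (control, treated).
#' @param N1,N2 positive library sizes (clean-read totals) of the
#'   control and treated libraries.
#' @return p-value in (0, 1].
#' @export
count_p_value <- function(x, y, N1, N2) {
  if (length(x) != 1L || length(y) != 1L)
    return(mapply(count_p_value, x, y, MoreArgs = list(N1 = N1, N2 = N2)))
  if (x < 0 || y < 0) stop("counts must be non-negative")
  if (N1 <= 0 || N2 <= 0) stop("library sizes must be positive")
  r <- N2 / N1
  logr <- log(r)
  log1pr <- log1p(r)
  lower <- .logsumexp(.ac_log_term(0:y, x, logr, log1pr))
  # upper tail: extend the summation window until terms are negligible
  width <- max(64, ceiling(10 * sqrt(x + y + 1)))
  repeat {
    ks <- y:(y + width)
    lt <- .ac_log_term(ks, x, logr, log1pr)
    if (lt[length(lt)] < max(lt) - 45 || width > 1e7) break
    width <- width * 2L
  }
  upper <- .logsumexp(lt)
  min(1, 2 * min(exp(lower), exp(upper)))
}

#' Pearson correlation between replicate expression vectors
#'
#' @param countsA,countsB equal-length numeric vectors of per-miRNA
#'   normalized expressions in two replicates.
#' @return Pearson correlation coefficient in [-1, 1].
#' @export
replicate_pearson <- function(countsA, countsB) {
  if (length(countsA) != length(countsB))
    stop("replicate vectors must have equal length")
  if (length(countsA) < 2L)
    stop("need at least two values per replicate")
  if (stats::sd(countsA) == 0 || stats::sd(countsB) == 0)
    stop("undefined correlation: constant replicate vector")
  cor(countsA, countsB)
}

#' Differential expression table from a count matrix
#'
#' Replicate counts are pooled per strain (and totals summed), pooled
#' counts normalized with the zero substitution, and every miRNA whose
#' per-library normalized expression is below 1 in all libraries is
#' dropped.  Fold-change is \code{log2(treated / control)} of pooled
#' normalized expressions; the p-value is \code{\link{count_p_value}} on
#' pooled raw counts with the pooled clean-read totals.
#'
#' @param counts integer matrix (miRNAs x libraries) of raw counts, or a
#'   data.frame whose first column is the miRNA name.
#' @param totals named numeric vector of per-library clean-read totals.
#' @param groups list with character vectors \code{control} and
#'   \code{treated} naming the libraries of each strain.
#' @param alpha significance threshold on the p-value.
#' @param min_norm per-library normalized-expression floor below which a
#'   miRNA is ignored (paper rule: < 1 in all libraries).
#' @return data.frame of class \code{de_table}, sorted by p-value:
#'   \code{mirna}, \code{treated_count}, \code{control_count},
#'   \code{treated_norm}, \code{control_norm}, \code{fold_change},
#'   \code{p_value}, \code{significant}.
#' @export
de_table <- function(counts, totals, groups, alpha = 0.05,
                     min_norm = 1) {
  if (is.data.frame(counts)) {
    rn <- counts[[1L]]
    counts <- as.matrix(counts[, -1L, drop = FALSE])
    rownames(counts) <- rn
  }
  stopifnot(is.list(groups), all(c("control", "treated") %in% names(groups)))
  libs <- c(groups$control, groups$treated)
  if (!all(libs %in% colnames(counts)))
    stop("groups name libraries absent from the count matrix")
  if (!all(libs %in% names(totals)))
    stop("totals missing for some libraries")
  if (nrow(counts) == 0L)
    return(structure(data.frame(mirna = character(0),
                                treated_count = integer(0),
                                control_count = integer(0),
                                treated_norm = numeric(0),
                                control_norm = numeric(0),
                                fold_change = numeric(0),
                                p_value = numeric(0),
                                significant = logical(0)),
                     class = c("de_table", "data.frame")))
  # low-expression filter on per-library normalized values
  norm_lib <- sweep(counts[, libs, drop = FALSE], 2, totals[libs], "/") * 1e6
  keep <- apply(norm_lib, 1L, max) >= min_norm
  counts <- counts[keep, , drop = FALSE]
  ctrl <- rowSums(counts[, groups$control, drop = FALSE])
  trt <- rowSums(counts[, groups$treated, drop = FALSE])
  N1 <- sum(totals[groups$control])
  N2 <- sum(totals[groups$treated])
  cn <- normalize_expression(ctrl, N1)
  tn <- normalize_expression(trt, N2)
  fc <- fold_change(tn, cn)
  p <- vapply(seq_along(ctrl),
              function(i) count_p_value(ctrl[i], trt[i], N1, N2), 0)
  out <- data.frame(mirna = rownames(counts),
                    treated_count = as.integer(trt),
                    control_count = as.integer(ctrl),
                    treated_norm = tn, control_norm = cn,
                    fold_change = fc, p_value = p,
                    significant = p < alpha,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$mirna, method = "radix"), ]
  rownames(out) <- NULL
  class(out) <- c("de_table", "data.frame")
  out
}
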