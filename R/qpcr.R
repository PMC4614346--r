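# qPCR validation arithmetic: relative expression versus the U6 snRNA
# reference and a two-sample strain comparison.

#' Relative expression from threshold cycles
#'
#' \code{2^-(ct_mirna - ct_u6)}: the expression of a miRNA relative to
#' the U6 snRNA internal reference.  Adding a constant to both CTs
#' leaves the result unchanged.
#'
#' @param ct_mirna,ct_u6 finite threshold cycle values (vectorized).
#' @return positive relative expression.
#' @export
relative_expression <- function(ct_mirna, ct_u6) {
  if (any(!is.finite(ct_mirna)) || any(!is.finite(ct_u6)))
    stop("CT values must be finite")
  2^(-(ct_mirna - ct_u6))
}

#' Compare relative expression between two strains
#'
#' Two-sample two-sided t-test (equal-variance by default, the classic
#' SAS-style choice; set \code{var_equal = FALSE} for Welch).
#'
#' @param groupA,groupB numeric vectors of relative expressions, at
#'   least two values each.
#' @param var_equal assume equal variances.
#' @return list with \code{t}, \code{p_value}, \code{significant_05},
#'   \code{significant_01}.
#' @export
compare_strains <- function(groupA, groupB, var_equal = TRUE) {
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("each group needs at least two values")
  tt <- t.test(groupA, groupB, var.equal = var_equal)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       significant_05 = tt$p.value < 0.05,
       significant_01 = tt$p.value < 0.01)
}

#' qPCR validation table
#'
#' Computes per-sample relative expression and, per miRNA, the
#' two-strain comparison.
#'
#' @param ct data.frame with columns \code{sample}, \code{strain},
#'   \code{mirna}, \code{ct_mirna}, \code{ct_u6}; exactly two strain
#'   levels.
#' @param var_equal passed to \code{\link{compare_strains}}.
#' @return list with \code{measurements} (input plus
#'   \code{relative_expression}) and \code{tests} (per-miRNA t-test
#'   results).
#' @export
qpcr_table <- function(ct, var_equal = TRUE) {
  stopifnot(all(c("sample", "strain", "mirna", "ct_mirna", "ct_u6") %in%
                  names(ct)))
  strains <- sort(unique(ct$strain))
  if (length(strains) != 2L) stop("expected exactly two strains")
  ct$relative_expression <- relative_expression(ct$ct_mirna, ct$ct_u6)
  tests <- lapply(sort(unique(ct$mirna)), function(mi) {
    sub <- ct[ct$mirna == mi, ]
    res <- compare_strains(
      sub$relative_expression[sub$strain == strains[1L]],
      sub$relative_expression[sub$strain == strains[2L]],
      var_equal = var_equal)
    data.frame(mirna = mi, t = res$t, p_value = res$p_value,
               significant_05 = res$significant_05,
               significant_01 = res$significant_01,
               stringsAsFactors = FALSE)
  })
  list(measurements = ct, tests = do.call(rbind, tests))
}
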