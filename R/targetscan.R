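# miRNA target prediction on transcripts: plant-style complementarity
# penalty scoring (Allen/Schwab rules) plus duplex hybridization energy
# under the same stacking model as the hairpin module.

#' Target-scan thresholds
#'
#' @param max_penalty maximum accepted complementarity penalty score.
#' @param max_energy maximum accepted duplex hybridization energy
#'   (kcal/mol).
#' @param core core region of the miRNA (positions from the 5' end, both
#'   ends inclusive) in which penalties are doubled.
#' @return list of class \code{target_thresholds}.
#' @export
target_thresholds <- function(max_penalty = 4.0, max_energy = -20,
                              core = c(2L, 13L)) {
  structure(list(max_penalty = max_penalty, max_energy = max_energy,
                 core = as.integer(core)),
            class = "target_thresholds")
}

# per-position penalty lookup: rows = miRNA base code, cols = transcript
# site base code (both DNA codes; complement = 0, G.U wobble = 0.5,
# anything else = 1)
.penalty_lookup <- function() {
  pen <- matrix(1, 4, 4)
  pen[1, 4] <- 0  # A:T
  pen[2, 3] <- 0  # C:G
  pen[3, 2] <- 0  # G:C
  pen[4, 1] <- 0  # T:A
  pen[3, 4] <- 0.5  # G:U wobble (G with T on the transcript)
  pen[4, 3] <- 0.5  # U:G wobble
  pen
}

#' Complementarity penalty score of a miRNA/site alignment
#'
#' The site is the transcript subsequence (5'->3'); the miRNA pairs with
#' it antiparallel, so miRNA position i faces site position
#' \code{L - i + 1}.  Each mismatch or gap scores 1, each G.U wobble
#' 0.5, and scores are doubled at miRNA positions 2--13 (the core).
#' Gaps are written as \code{"-"} in either sequence (equal lengths
#' after gapping).
#'
#' @param mirna miRNA sequence, 5'->3'.
#' @param site transcript site sequence, 5'->3', same length as
#'   \code{mirna} after gapping.
#' @param core core positions (from the miRNA 5' end) with doubled
#'   weight.
#' @return non-negative penalty score; 0 iff the site is the exact
#'   reverse complement.
#' @export
penalty_score <- function(mirna, site, core = c(2L, 13L)) {
  if (!nzchar(mirna) || !nzchar(site)) stop("empty sequence")
  if (nchar(mirna) != nchar(site))
    stop("mirna and site must have equal length after gapping")
  m <- strsplit(.normalize_seq(mirna), "")[[1L]]
  s <- rev(strsplit(.normalize_seq(site), "")[[1L]])
  pen <- .penalty_lookup()
  L <- length(m)
  w <- ifelse(seq_len(L) >= core[1L] & seq_len(L) <= core[2L], 2, 1)
  total <- 0
  for (i in seq_len(L)) {
    if (m[i] == "-" || s[i] == "-") {
      total <- total + 1 * w[i]
    } else {
      a <- match(m[i], c("A", "C", "G", "T"))
      b <- match(s[i], c("A", "C", "G", "T"))
      if (is.na(a) || is.na(b)) stop("non-nucleotide character")
      total <- total + pen[a, b] * w[i]
    }
  }
  total
}

#' Duplex hybridization energy of a miRNA/site pair
#'
#' Minimum stacking energy over all ungapped antiparallel alignments of
#' the miRNA against the site, with no intramolecular pairs; within an
#' alignment, any subset of pairable positions may form pairs and the
#' energy is the sum of stacks between adjacent formed pairs (same
#' nearest-neighbor table as the hairpin module).  Always <= 0.
#'
#' @param mirna,site nucleotide sequences (lengths <= 30).
#' @return duplex energy in kcal/mol.
#' @export
duplex_mfe <- function(mirna, site) {
  a <- seq_to_codes(mirna)
  b <- rev(seq_to_codes(site))  # antiparallel
  la <- length(a); lb <- length(b)
  if (la > 30L || lb > 30L) stop("duplex sequences must be <= 30 nt")
  best <- 0
  for (off in (-(la - 1L)):(lb - 1L)) {
    is <- max(1L, 1L - off):min(la, lb - off)
    if (length(is) < 2L) next
    q <- .PAIR_INDEX[cbind(a[is], b[is + off])]
    # stack edge between consecutive aligned positions both paired
    np <- length(is)
    g0 <- 0; g1 <- if (q[1L] > 0L) 0 else Inf
    for (t in 2L:np) {
      edge <- if (q[t - 1L] > 0L && q[t] > 0L)
        .STACK_ENERGY[q[t - 1L], q[t]] else Inf
      n1 <- if (q[t] > 0L) min(g0, g1 + edge) else Inf
      n0 <- min(g0, g1)
      g0 <- n0; g1 <- n1
    }
    best <- min(best, g0, g1)
  }
  best
}

#' Scan transcripts for miRNA target sites
#'
#' Every window of each transcript is scored with
#' \code{\link{penalty_score}}; windows passing the penalty threshold
#' are scored with \code{\link{duplex_mfe}} and must also pass the
#' energy threshold.  Overlapping passing sites of one miRNA on one
#' transcript are merged to the best-scoring one (penalty, then energy,
#' then leftmost).  Output order is deterministic and independent of
#' input order.
#'
#' @param mirnas named character vector of miRNA sequences.
#' @param transcripts named character vector of transcript sequences.
#' @param thresholds a \code{\link{target_thresholds}}.
#' @return data.frame: \code{mirna}, \code{transcript}, \code{start},
#'   \code{end} (site span, 0-based half-open), \code{site},
#'   \code{penalty}, \code{energy}.
#' @export
scan_targets <- function(mirnas, transcripts,
                         thresholds = target_thresholds()) {
  stopifnot(!is.null(names(mirnas)), !is.null(names(transcripts)))
  pen <- .penalty_lookup()
  rows <- list()
  for (mn in sort(names(mirnas), method = "radix")) {
    mseq <- .normalize_seq(mirnas[[mn]])
    mc <- seq_to_codes(mseq)
    m <- length(mc)
    w <- ifelse(seq_len(m) >= thresholds$core[1L] &
                  seq_len(m) <= thresholds$core[2L], 2, 1)
    for (tn in sort(names(transcripts), method = "radix")) {
      tseq <- .normalize_seq(transcripts[[tn]])
      tc <- seq_to_codes(tseq)
      nw <- length(tc) - m + 1L
      if (nw < 1L) next
      total <- numeric(nw)
      for (i in seq_len(m)) {
        # miRNA position i faces site position m - i + 1
        slice <- tc[(seq_len(nw)) + (m - i)]
        total <- total + pen[cbind(mc[i], slice)] * w[i]
      }
      hits <- which(total <= thresholds$max_penalty)
      if (!length(hits)) next
      cand <- data.frame(start = hits - 1L, penalty = total[hits])
      cand$site <- substr(rep(tseq, nrow(cand)), hits, hits + m - 1L)
      cand$energy <- vapply(cand$site, function(s) duplex_mfe(mseq, s),
                            0, USE.NAMES = FALSE)
      cand <- cand[cand$energy <= thresholds$max_energy, , drop = FALSE]
      if (!nrow(cand)) next
      # merge overlapping sites: best penalty, then energy, then leftmost
      cand <- cand[order(cand$penalty, cand$energy, cand$start), ,
                   drop = FALSE]
      kept <- integer(0)
      for (k in seq_len(nrow(cand))) {
        s <- cand$start[k]
        if (!any(abs(cand$start[kept] - s) < m)) kept <- c(kept, k)
      }
      cand <- cand[kept, , drop = FALSE]
      cand <- cand[order(cand$start), , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        mirna = mn, transcript = tn, start = cand$start,
        end = cand$start + m, site = cand$site, penalty = cand$penalty,
        energy = cand$energy, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(mirna = character(0), transcript = character(0),
                      start = integer(0), end = integer(0),
                      site = character(0), penalty = numeric(0),
                      energy = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
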