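# Novel miRNA discovery: map unannotated tags to a genome, excise
# candidate precursors, fold them and apply hairpin / Dicer / MFE
# acceptance criteria.

#' Hairpin acceptance criteria
#'
#' @param max_mfe maximum (most positive) accepted precursor minimum free
#'   energy, kcal/mol.
#' @param min_paired_frac minimum fraction of mature bases paired against
#'   the opposite arm.
#' @param mature_len allowed mature length range (closed).
#' @param min_support minimum total read support for a candidate tag.
#' @param up,down nt excised upstream/downstream of a 5'-arm tag (the
#'   3'-arm window is mirrored); chosen to reproduce 60--100 nt
#'   precursors.
#' @param max_precursor maximum precursor length (nt).
#' @return list of class \code{hairpin_criteria}.
#' @export
hairpin_criteria <- function(max_mfe = -18, min_paired_frac = 0.75,
                             mature_len = c(20L, 24L), min_support = 3L,
                             up = 15L, down = 85L, max_precursor = 100L) {
  structure(list(max_mfe = max_mfe, min_paired_frac = min_paired_frac,
                 mature_len = as.integer(mature_len),
                 min_support = as.integer(min_support),
                 up = as.integer(up), down = as.integer(down),
                 max_precursor = as.integer(max_precursor)),
            class = "hairpin_criteria")
}

#' Map tags to a genome by perfect matching on both strands
#'
#' All exact occurrences are reported; reverse-strand matches are
#' reported against the reverse complement, with the locus in forward
#' 0-based half-open coordinates.
#'
#' @param seqs character vector of tag sequences.
#' @param genome named character vector of contig sequences.
#' @return data.frame \code{tag}, \code{contig}, \code{strand},
#'   \code{start}, \code{end} (0-based half-open).
#' @export
map_unannotated <- function(seqs, genome) {
  rows <- list()
  cnames <- sort(names(genome), method = "radix")
  for (tag in seqs) {
    L <- nchar(tag)
    rctag <- revcomp(tag)
    for (cn in cnames) {
      for (strand in c("+", "-")) {
        query <- if (strand == "+") tag else rctag
        m <- gregexpr(query, genome[[cn]], fixed = TRUE)[[1L]]
        if (m[1L] == -1L) next
        for (p in as.integer(m)) {
          rows[[length(rows) + 1L]] <- data.frame(
            tag = tag, contig = cn, strand = strand,
            start = p - 1L, end = p - 1L + L, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows))
    return(data.frame(tag = character(0), contig = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Excise candidate precursor windows around a mapped tag
#'
#' Two windows are tried: tag on the 5' arm (\code{up} nt upstream +
#' \code{down} nt downstream of the tag start) and tag on the 3' arm
#' (mirrored).  Windows are clipped at contig boundaries rather than
#' erroring; every returned candidate contains the tag.
#'
#' @param placement one row of \code{\link{map_unannotated}} output.
#' @param genome named character vector of contigs.
#' @param criteria a \code{\link{hairpin_criteria}}.
#' @return data.frame \code{seq} (precursor in tag orientation),
#'   \code{contig}, \code{strand}, \code{start}, \code{end} (forward
#'   0-based half-open), \code{tag_offset} (0-based offset of the tag in
#'   the precursor), \code{arm_window} ("5p"/"3p").
#' @export
extract_precursors <- function(placement, genome,
                               criteria = hairpin_criteria()) {
  contig <- genome[[placement$contig]]
  L <- nchar(contig)
  taglen <- placement$end - placement$start
  # oriented coordinates: position of the tag on the strand it matched
  os <- if (placement$strand == "+") placement$start else
    L - placement$end
  oe <- os + taglen
  win <- criteria$up + criteria$down
  spans <- list(`5p` = c(os - criteria$up, os - criteria$up + win),
                `3p` = c(oe + criteria$up - win, oe + criteria$up))
  oriented <- if (placement$strand == "+") contig else revcomp(contig)
  out <- list()
  for (arm in names(spans)) {
    a <- max(spans[[arm]][1L], 0L)
    b <- min(spans[[arm]][2L], L)
    if (b - a < taglen) next
    seq <- substr(oriented, a + 1L, b)
    if (placement$strand == "+") {
      fs <- a; fe <- b
    } else {
      fs <- L - b; fe <- L - a
    }
    out[[arm]] <- data.frame(
      seq = seq, contig = placement$contig, strand = placement$strand,
      start = as.integer(fs), end = as.integer(fe),
      tag_offset = as.integer(os - a), arm_window = arm,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame()
  rownames(out) <- NULL
  unique(out)
}

# Trim an excised window to the single stem-loop containing the tag.
# Random genomic flanks in the fixed excision window frequently fold
# into small side hairpins that would fail the single-stem-loop
# criterion, so -- as hairpin finders do -- the candidate is refined to
# the maximal run of pairs that encloses exactly the tag's terminal
# loop, plus a small margin for the star overhang.  Returns
# list(seq, offset) or NULL when the tag is unpaired or its stem
# branches.
.stem_trim <- function(seq, tag, fold, margin = 3L) {
  pos <- as.integer(regexpr(tag, seq, fixed = TRUE))
  if (pos < 1L) return(NULL)
  m1 <- pos; m2 <- pos + nchar(tag) - 1L
  pairs <- fold$pairs
  tp <- (m1:m2)[pairs[m1:m2] > 0L]
  if (!length(tp)) return(NULL)
  t1 <- tp[1L]; q1 <- pairs[t1]
  lo <- min(t1, q1); hi <- max(t1, q1)
  loops <- .terminal_loops(pairs)
  n_inside <- function(i, j)
    sum(vapply(loops, function(l) l[1L] > i && l[2L] < j, TRUE))
  if (n_inside(lo, hi) != 1L) return(NULL)  # tag stem branches
  opens <- which(pairs > seq_along(pairs))
  chain <- opens[opens <= lo & pairs[opens] >= hi]
  chain <- chain[vapply(chain, function(i) n_inside(i, pairs[i]) == 1L,
                        TRUE)]
  if (!length(chain)) return(NULL)
  a <- max(1L, min(chain) - margin)
  b <- min(nchar(seq), max(pairs[chain]) + margin)
  list(seq = substr(seq, a, b), offset = a - 1L)
}

# hairpin loops of a partner vector: pairs with no pair strictly inside
.terminal_loops <- function(pairs) {
  loops <- list()
  for (i in seq_along(pairs)) {
    j <- pairs[i]
    if (j <= i) next
    if (j == i + 1L || all(pairs[(i + 1L):(j - 1L)] == 0L))
      loops[[length(loops) + 1L]] <- c(i + 1L, j - 1L)
  }
  loops
}

#' Evaluate a candidate precursor against the hairpin criteria
#'
#' Acceptance requires: MFE at or below \code{max_mfe}; a single
#' stem-loop (exactly one terminal loop); at least
#' \code{min_paired_frac} of mature bases paired; the mature not
#' spanning the terminal loop; a star region with the 2-nt 3' overhang
#' characteristic of Dicer processing; and mature length within
#' \code{mature_len}.
#'
#' @param precursor precursor sequence (tag orientation).
#' @param tag mature candidate sequence (must occur in the precursor).
#' @param fold a \code{\link{fold_mfe}} result for \code{precursor}.
#' @param criteria a \code{\link{hairpin_criteria}}.
#' @return list with \code{accept} (logical); on acceptance also
#'   \code{arm} ("5p"/"3p"), \code{star}, \code{mature_start} (0-based
#'   offset); on rejection \code{reason} (one of "length", "mfe",
#'   "multiloop", "pairing", "loop_span", "star").
#' @export
evaluate_hairpin <- function(precursor, tag, fold,
                             criteria = hairpin_criteria()) {
  taglen <- nchar(tag)
  if (taglen < criteria$mature_len[1L] || taglen > criteria$mature_len[2L])
    return(list(accept = FALSE, reason = "length"))
  pos <- regexpr(tag, precursor, fixed = TRUE)
  if (pos < 1L) stop("tag does not occur in the candidate precursor")
  if (fold$mfe > criteria$max_mfe)
    return(list(accept = FALSE, reason = "mfe"))
  pairs <- fold$pairs
  loops <- .terminal_loops(pairs)
  if (length(loops) != 1L)
    return(list(accept = FALSE, reason = "multiloop"))
  m1 <- as.integer(pos); m2 <- m1 + taglen - 1L
  mp <- pairs[m1:m2]
  if (mean(mp > 0L) < criteria$min_paired_frac)
    return(list(accept = FALSE, reason = "pairing"))
  loop <- loops[[1L]]
  if (loop[2L] >= loop[1L] && m1 < loop[1L] && m2 > loop[2L])
    return(list(accept = FALSE, reason = "loop_span"))
  # Dicer criterion: both mature ends anchored in the duplex, star =
  # partner region shifted by the 2-nt 3' overhang
  paired_pos <- (m1:m2)[mp > 0L]
  first_p <- paired_pos[1L]; last_p <- paired_pos[length(paired_pos)]
  if (first_p > m1 + 2L || last_p < m2 - 2L)
    return(list(accept = FALSE, reason = "star"))
  s1 <- pairs[last_p] + 2L
  s2 <- pairs[first_p] + 2L
  lo <- min(s1, s2); hi <- max(s1, s2)
  if (lo < 1L || hi > nchar(precursor) ||
      (lo <= m2 && hi >= m1 && !(hi < m1 || lo > m2)))
    return(list(accept = FALSE, reason = "star"))
  arm <- if (m2 < loop[1L]) "5p" else if (m1 > loop[2L]) "3p" else NA
  if (is.na(arm))
    return(list(accept = FALSE, reason = "loop_span"))
  list(accept = TRUE, arm = arm,
       star = substr(precursor, lo, hi),
       mature_start = m1 - 1L)
}

#' Name and deduplicate accepted hairpin candidates
#'
#' Sequential zero-padded names of the form \code{Ofu-m0001_5p}.
#' Identical (mature, precursor) pairs at different loci are retained as
#' separate records; exact duplicate records (same locus) are collapsed.
#'
#' @param accepted data.frame of accepted candidates with columns
#'   \code{mature}, \code{seq}, \code{contig}, \code{strand},
#'   \code{start}, \code{end}, \code{arm}, ...
#' @param prefix name prefix.
#' @return the data.frame with a \code{name} column, ordered by locus.
#' @export
name_candidates <- function(accepted, prefix = "Ofu-m") {
  if (!nrow(accepted)) {
    accepted$name <- character(0)
    return(accepted)
  }
  key <- c("mature", "seq", "contig", "strand", "start", "end")
  accepted <- accepted[!duplicated(accepted[, key]), , drop = FALSE]
  ord <- order(accepted$contig, accepted$start, accepted$strand,
               accepted$mature, method = "radix")
  accepted <- accepted[ord, , drop = FALSE]
  accepted$name <- sprintf("%s%04d_%s", prefix, seq_len(nrow(accepted)),
                           accepted$arm)
  rownames(accepted) <- NULL
  accepted
}

#' Discover novel miRNAs from unannotated tags
#'
#' Runs the full candidate path: support and length filtering, perfect
#' genome mapping, precursor excision, MFE folding and hairpin
#' evaluation, then naming.
#'
#' @param tags tag data.frame (\code{sequence} + count columns) of
#'   unannotated tags.
#' @param genome named character vector of contigs.
#' @param criteria a \code{\link{hairpin_criteria}}.
#' @return data.frame of named candidates: \code{name}, \code{mature},
#'   \code{mature_len}, \code{contig}, \code{strand}, \code{start},
#'   \code{end} (precursor locus, 0-based half-open),
#'   \code{mature_start}, \code{mature_end}, \code{precursor_len},
#'   \code{seq} (precursor), \code{structure}, \code{mfe}, \code{arm},
#'   \code{star}, plus the per-library counts of the mature tag.
#' @export
find_novel_mirnas <- function(tags, genome,
                              criteria = hairpin_criteria()) {
  counts <- tag_counts(tags)
  libs <- colnames(counts)
  empty <- data.frame(name = character(0), mature = character(0),
                      mature_len = integer(0), contig = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), mature_start = integer(0),
                      mature_end = integer(0), precursor_len = integer(0),
                      seq = character(0), structure = character(0),
                      mfe = numeric(0), arm = character(0),
                      star = character(0), stringsAsFactors = FALSE)
  for (l in libs) empty[[l]] <- integer(0)
  lens <- nchar(tags$sequence)
  keep <- rowSums(counts) >= criteria$min_support &
    lens >= criteria$mature_len[1L] & lens <= criteria$mature_len[2L]
  if (!any(keep)) return(empty)
  placements <- map_unannotated(tags$sequence[keep], genome)
  if (!nrow(placements)) return(empty)
  rows <- list()
  for (i in seq_len(nrow(placements))) {
    pl <- placements[i, ]
    cands <- extract_precursors(pl, genome, criteria)
    if (!nrow(cands)) next
    for (k in seq_len(nrow(cands))) {
      cand <- cands[k, ]
      pseq <- cand$seq
      pstart <- cand$start; pend <- cand$end
      fold <- fold_mfe(pseq)
      ev <- evaluate_hairpin(pseq, pl$tag, fold, criteria)
      if (!isTRUE(ev$accept) &&
          ev$reason %in% c("multiloop", "star", "loop_span", "pairing")) {
        # refine: trim the window to the tag's stem-loop and refold
        tr <- .stem_trim(pseq, pl$tag, fold)
        if (!is.null(tr) && nchar(tr$seq) >= 40L) {
          if (pl$strand == "+") {
            pstart <- cand$start + tr$offset
            pend <- pstart + nchar(tr$seq)
          } else {
            pend <- cand$end - tr$offset
            pstart <- pend - nchar(tr$seq)
          }
          pseq <- tr$seq
          fold <- fold_mfe(pseq)
          ev <- evaluate_hairpin(pseq, pl$tag, fold, criteria)
        }
      }
      if (!isTRUE(ev$accept)) next
      taglen <- nchar(pl$tag)
      # mature locus in forward coordinates
      if (pl$strand == "+") {
        ms <- pstart + ev$mature_start
      } else {
        ms <- pend - ev$mature_start - taglen
      }
      rec <- data.frame(
        mature = pl$tag, mature_len = taglen, contig = cand$contig,
        strand = cand$strand, start = as.integer(pstart),
        end = as.integer(pend),
        mature_start = as.integer(ms),
        mature_end = as.integer(ms + taglen),
        precursor_len = nchar(pseq), seq = pseq,
        structure = fold$structure, mfe = fold$mfe, arm = ev$arm,
        star = ev$star, stringsAsFactors = FALSE)
      ci <- match(pl$tag, tags$sequence)
      for (l in libs) rec[[l]] <- counts[ci, l]
      rows[[length(rows) + 1L]] <- rec
      break  # at most one accepted window per placement
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  # a hairpin is its own reverse complement's hairpin: the same tag can
  # re-map against the opposite arm and yield a mirrored candidate at
  # the same locus -- keep the better-scoring strand
  ord <- order(out$mature, out$contig, out$mfe, out$strand,
               method = "radix")
  out <- out[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    j <- which(keep & seq_len(nrow(out)) < i &
                 out$mature == out$mature[i] &
                 out$contig == out$contig[i] &
                 out$start < out$end[i] & out$end > out$start[i])
    if (length(j)) keep[i] <- FALSE
  }
  name_candidates(out[keep, , drop = FALSE])
}
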