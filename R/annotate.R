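# Tag annotation: each unique tag is assigned to exactly one category by
# the priority rule
#   rRNAetc (GenBank before Rfam classes) > known miRNA > repeat > exon
#   > intron > unann.
# Non-coding RNA categories match by exact substring containment in the
# reference sequences; known miRNAs match by near-exact alignment to the
# mature region of a precursor (+-2 nt end shifts, <= 2 mismatches, no
# indels), mirroring common miRBase-pipeline practice.

#' Known-miRNA matching tolerance
#'
#' @param max_shift maximum shift of either tag end relative to the
#'   mature reference ends on the precursor (nt).
#' @param max_mismatch maximum number of mismatches (no indels).
#' @return list of class \code{mirna_tolerance}.
#' @export
mirna_tolerance <- function(max_shift = 2L, max_mismatch = 2L) {
  structure(list(max_shift = as.integer(max_shift),
                 max_mismatch = as.integer(max_mismatch)),
            class = "mirna_tolerance")
}

# Locate each mature reference within a precursor.  Falls back to the
# mature sequence itself when no precursor contains it.
.mature_context <- function(mature, precursor) {
  pnames <- if (length(precursor))
    sort(names(precursor), method = "radix") else character(0)
  out <- vector("list", length(mature))
  names(out) <- names(mature)
  for (nm in names(mature)) {
    m <- mature[[nm]]
    ctx <- NULL
    for (pn in pnames) {
      p <- regexpr(m, precursor[[pn]], fixed = TRUE)
      if (p > 0L) {
        ctx <- list(ref = nm, precursor = pn, seq = precursor[[pn]],
                    start = as.integer(p),
                    end = as.integer(p) + nchar(m) - 1L)
        break
      }
    }
    if (is.null(ctx))
      ctx <- list(ref = nm, precursor = nm, seq = m, start = 1L,
                  end = nchar(m))
    out[[nm]] <- ctx
  }
  out
}

#' Match tags against a known miRNA database
#'
#' A tag hits a mature miRNA when it aligns on the precursor with both
#' ends within \code{max_shift} nt of the mature ends and at most
#' \code{max_mismatch} mismatches (no indels).  Variants of one reference
#' are pooled under one name; the representative sequence is the variant
#' with the highest total count.  Assigned names carry the species prefix
#' (default \code{"Ofu-"}).
#'
#' @param tags tag data.frame (\code{sequence} + count columns).
#' @param mature named character vector of mature reference sequences.
#' @param precursor named character vector of precursor sequences.
#' @param tolerance a \code{\link{mirna_tolerance}}.
#' @param prefix species prefix prepended to reference names.
#' @return list with \code{hits} (one row per reference hit: \code{name},
#'   \code{reference}, \code{representative}, count columns pooled over
#'   variants, \code{n_variants}) and \code{tag_map} (data.frame
#'   \code{sequence}, \code{reference}, \code{mismatches}, \code{shift}).
#' @export
match_known_mirnas <- function(tags, mature, precursor = character(0),
                               tolerance = mirna_tolerance(),
                               prefix = "Ofu-") {
  stopifnot(length(mature) > 0L, !is.null(names(mature)))
  mature <- vapply(mature, .normalize_seq, "")
  precursor <- if (length(precursor))
    vapply(precursor, .normalize_seq, "") else character(0)
  ctx <- .mature_context(mature, precursor)
  sh <- tolerance$max_shift
  counts <- tag_counts(tags)
  seqs <- tags$sequence
  tlen <- nchar(seqs)

  # exact-variant dictionary: all 0-mismatch windows within the allowed
  # end shifts map straight to their reference
  dict <- new.env(parent = emptyenv(), hash = TRUE)
  for (nm in sort(names(ctx), method = "radix")) {
    cc <- ctx[[nm]]
    for (s in -sh:sh) for (e in -sh:sh) {
      a <- cc$start + s; b <- cc$end + e
      if (a < 1L || b > nchar(cc$seq) || b - a + 1L < 10L) next
      key <- substr(cc$seq, a, b)
      prev <- dict[[key]]
      cand <- list(ref = nm, mm = 0L, shift = abs(s) + abs(e))
      if (is.null(prev) || cand$shift < prev$shift ||
          (cand$shift == prev$shift && cand$ref < prev$ref))
        dict[[key]] <- cand
    }
  }
  hit_ref <- rep(NA_character_, length(seqs))
  hit_mm <- rep(NA_integer_, length(seqs))
  hit_shift <- rep(NA_integer_, length(seqs))
  for (i in seq_along(seqs)) {
    h <- dict[[seqs[i]]]
    if (!is.null(h)) {
      hit_ref[i] <- h$ref; hit_mm[i] <- 0L; hit_shift[i] <- h$shift
    }
  }
  # mismatch path for the remainder, vectorized per (reference, shift,
  # tag length) group
  rest <- which(is.na(hit_ref))
  if (length(rest) && tolerance$max_mismatch > 0L) {
    bylen <- split(rest, tlen[rest])
    for (nm in sort(names(ctx), method = "radix")) {
      cc <- ctx[[nm]]
      for (s in -sh:sh) {
        a <- cc$start + s
        if (a < 1L) next
        for (L in as.integer(names(bylen))) {
          b <- a + L - 1L
          e <- b - cc$end
          if (abs(e) > sh || b > nchar(cc$seq)) next
          idx <- bylen[[as.character(L)]]
          refsub <- substr(cc$seq, a, b)
          rch <- strsplit(refsub, "")[[1L]]
          sq <- seqs[idx]
          mm <- integer(length(idx))
          for (j in seq_len(L))
            mm <- mm + (substr(sq, j, j) != rch[j])
          ok <- mm <= tolerance$max_mismatch
          if (!any(ok)) next
          shift <- abs(s) + abs(e)
          for (k in which(ok)) {
            i <- idx[k]
            better <- is.na(hit_ref[i]) || mm[k] < hit_mm[i] ||
              (mm[k] == hit_mm[i] && (shift < hit_shift[i] ||
                 (shift == hit_shift[i] && nm < hit_ref[i])))
            if (better) {
              hit_ref[i] <- nm; hit_mm[i] <- mm[k]; hit_shift[i] <- shift
            }
          }
        }
      }
    }
  }

  matched <- which(!is.na(hit_ref))
  tag_map <- data.frame(sequence = seqs[matched],
                        reference = hit_ref[matched],
                        mismatches = hit_mm[matched],
                        shift = hit_shift[matched],
                        stringsAsFactors = FALSE)
  libs <- colnames(counts)
  if (length(matched)) {
    refs <- sort(unique(hit_ref[matched]), method = "radix")
    hits <- data.frame(name = paste0(prefix, refs), reference = refs,
                       stringsAsFactors = FALSE)
    pooled <- matrix(0L, length(refs), length(libs),
                     dimnames = list(refs, libs))
    rep_seq <- character(length(refs))
    for (r in seq_along(refs)) {
      idx <- matched[hit_ref[matched] == refs[r]]
      sub <- counts[idx, , drop = FALSE]
      pooled[r, ] <- as.integer(colSums(sub))
      tot <- rowSums(sub)
      best <- idx[order(-tot, seqs[idx], method = "radix")][1L]
      rep_seq[r] <- seqs[best]
      hits$n_variants[r] <- length(idx)
    }
    hits$representative <- rep_seq
    hits <- cbind(hits, as.data.frame(pooled))
    rownames(hits) <- NULL
  } else {
    hits <- data.frame(name = character(0), reference = character(0),
                       n_variants = integer(0),
                       representative = character(0),
                       stringsAsFactors = FALSE)
    for (l in libs) hits[[l]] <- integer(0)
  }
  list(hits = hits, tag_map = tag_map)
}

# Which tags are substrings of any sequence in `refs`?  Returns the name
# of the first containing reference (sorted order) or NA.
.substring_ref <- function(seqs, refs) {
  out <- rep(NA_character_, length(seqs))
  if (!length(refs) || !length(seqs)) return(out)
  rnames <- sort(names(refs), method = "radix")
  concat <- paste(refs[rnames], collapse = "#")
  inany <- vapply(seqs, function(s) grepl(s, concat, fixed = TRUE),
                  TRUE, USE.NAMES = FALSE)
  for (i in which(inany)) {
    for (rn in rnames) {
      if (grepl(seqs[i], refs[[rn]], fixed = TRUE)) {
        out[i] <- rn
        break
      }
    }
  }
  out
}

#' Classify tags into annotation categories by the priority rule
#'
#' Categories are tried in order: the non-coding RNA classes in
#' \code{ncrna} (list order = priority; GenBank-derived sets should come
#' before Rfam-derived ones), then known miRNAs, then any optional
#' genomic categories (repeat/exon/intron), and finally \code{unann}.
#' A tag matching several categories keeps only the highest-priority one.
#'
#' @param tags tag data.frame (\code{sequence} + count columns).
#' @param ncrna named list of character vectors of reference sequences,
#'   in priority order (e.g. \code{list(rRNA_gb = ..., rRNA = ...,
#'   tRNA = ..., snRNA = ..., snoRNA = ...)}).
#' @param mature,precursor known miRNA database (see
#'   \code{\link{match_known_mirnas}}); may be empty.
#' @param genomic optional named list of further category reference sets
#'   (matched after known miRNAs); categories absent from the list are
#'   skipped.
#' @param tolerance a \code{\link{mirna_tolerance}}.
#' @param prefix species prefix for known miRNA names.
#' @return list with \code{assignment} (data.frame \code{sequence},
#'   \code{category}, \code{reference}), \code{known} (the
#'   \code{\link{match_known_mirnas}} result), and \code{composition}
#'   (per-category unique-tag and per-library total-read counts).
#' @export
classify_tags <- function(tags, ncrna = list(), mature = character(0),
                          precursor = character(0), genomic = list(),
                          tolerance = mirna_tolerance(),
                          prefix = "Ofu-") {
  seqs <- tags$sequence
  counts <- tag_counts(tags)
  category <- rep("unann", length(seqs))
  reference <- rep(NA_character_, length(seqs))
  unassigned <- seq_along(seqs)
  for (cls in names(ncrna)) {
    if (!length(unassigned)) break
    refs <- ncrna[[cls]]
    if (is.null(names(refs)))
      names(refs) <- paste0(cls, "_", seq_along(refs))
    ref <- .substring_ref(seqs[unassigned], refs)
    hit <- !is.na(ref)
    category[unassigned[hit]] <- cls
    reference[unassigned[hit]] <- ref[hit]
    unassigned <- unassigned[!hit]
  }
  empty_hits <- data.frame(name = character(0), reference = character(0),
                           n_variants = integer(0),
                           representative = character(0),
                           stringsAsFactors = FALSE)
  for (l in colnames(counts)) empty_hits[[l]] <- integer(0)
  known <- list(hits = empty_hits,
                tag_map = data.frame(sequence = character(0),
                                     reference = character(0),
                                     mismatches = integer(0),
                                     shift = integer(0),
                                     stringsAsFactors = FALSE))
  if (length(mature) && length(unassigned)) {
    known <- match_known_mirnas(tags[unassigned, , drop = FALSE],
                                mature, precursor, tolerance, prefix)
    if (nrow(known$tag_map)) {
      idx <- match(known$tag_map$sequence, seqs)
      category[idx] <- "known_miRNA"
      reference[idx] <- known$tag_map$reference
      unassigned <- setdiff(unassigned, idx)
    }
  }
  for (cls in names(genomic)) {
    if (!length(unassigned)) break
    refs <- genomic[[cls]]
    if (is.null(refs) || !length(refs)) next
    if (is.null(names(refs)))
      names(refs) <- paste0(cls, "_", seq_along(refs))
    ref <- .substring_ref(seqs[unassigned], refs)
    hit <- !is.na(ref)
    category[unassigned[hit]] <- cls
    reference[unassigned[hit]] <- ref[hit]
    unassigned <- unassigned[!hit]
  }
  cats <- c(names(ncrna), "known_miRNA", names(genomic), "unann")
  catf <- factor(category, levels = cats)
  comp <- data.frame(category = cats, unique = as.integer(table(catf)),
                     stringsAsFactors = FALSE)
  for (l in colnames(counts))
    comp[[l]] <- as.integer(tapply(counts[, l], catf, sum,
                                   default = 0L))
  list(assignment = data.frame(sequence = seqs, category = category,
                               reference = reference,
                               stringsAsFactors = FALSE),
       known = known, composition = comp)
}
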