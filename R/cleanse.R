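# Read-cleaning cascade and library accounting.
#
# Each high-quality read is assigned to exactly one category, tested in a
# fixed priority order so the categories partition the library:
#   low-quality (excluded from high-quality)
#   -> 5' adapter contaminant (read begins with the 5' adapter)
#   -> 3' adapter-null        (no 3' adapter match)
#   -> insert-null            (3' adapter starts at position 0)
#   -> polyA                  (insert with >= polyA_fraction A)
#   -> shorter-than-18
#   -> clean
# Clean inserts are the bases preceding the 3' adapter match; inserts
# longer than max_len are kept as clean but excluded from the 18-30 nt
# length histogram.

#' Cleaning parameters
#'
#' @param adapter_3p,adapter_5p adapter nucleotide strings (non-empty).
#' @param min_len,max_len retained insert length window (nt).
#' @param min_quality minimum per-base Phred score; any base below it
#'   marks the read low-quality.
#' @param max_n_frac maximum tolerated fraction of N bases.
#' @param polyA_fraction minimum A fraction for the polyA filter, in
#'   (0, 1].
#' @param adapter_min_overlap minimum 3' adapter prefix overlap (nt).
#' @param adapter_max_mismatch maximum mismatches in an adapter match.
#' @return validated list of class \code{clean_params}.
#' @export
clean_params <- function(adapter_3p, adapter_5p,
                         min_len = 18L, max_len = 30L,
                         min_quality = 5L, max_n_frac = 0.1,
                         polyA_fraction = 0.8,
                         adapter_min_overlap = 6L,
                         adapter_max_mismatch = 1L) {
  if (!is.character(adapter_3p) || !nzchar(adapter_3p))
    stop("configuration error: adapter_3p must be a non-empty string")
  if (!is.character(adapter_5p) || !nzchar(adapter_5p))
    stop("configuration error: adapter_5p must be a non-empty string")
  adapter_3p <- .normalize_seq(adapter_3p)
  adapter_5p <- .normalize_seq(adapter_5p)
  if (grepl("[^ACGT]", adapter_3p) || grepl("[^ACGT]", adapter_5p))
    stop("configuration error: adapters must be A/C/G/T strings")
  if (min_len > max_len)
    stop("configuration error: min_len must be <= max_len")
  if (polyA_fraction <= 0 || polyA_fraction > 1)
    stop("configuration error: polyA_fraction must be in (0, 1]")
  if (nchar(adapter_3p) < adapter_min_overlap)
    stop("configuration error: adapter_3p shorter than adapter_min_overlap")
  structure(list(adapter_3p = adapter_3p, adapter_5p = adapter_5p,
                 min_len = as.integer(min_len),
                 max_len = as.integer(max_len),
                 min_quality = as.integer(min_quality),
                 max_n_frac = max_n_frac,
                 polyA_fraction = polyA_fraction,
                 adapter_min_overlap = as.integer(adapter_min_overlap),
                 adapter_max_mismatch = as.integer(adapter_max_mismatch)),
            class = "clean_params")
}

# Leftmost 3' adapter match per read: >= min_overlap prefix overlap,
# <= max_mismatch mismatches.  Returns 1-based start positions (NA = no
# match).  Vectorized over reads via per-position character comparison.
find_adapter <- function(seqs, adapter, min_overlap = 6L,
                         max_mismatch = 1L) {
  n <- length(seqs)
  pos <- rep(NA_integer_, n)
  if (n == 0L) return(pos)
  lens <- nchar(seqs)
  alen <- nchar(adapter)
  achars <- strsplit(adapter, "")[[1L]]
  smax <- max(lens) - min_overlap + 1L
  if (smax < 1L) return(pos)
  undecided <- seq_len(n)
  for (s in seq_len(smax)) {
    undecided <- undecided[lens[undecided] - s + 1L >= min_overlap]
    if (!length(undecided)) break
    sq <- seqs[undecided]
    w <- pmin(alen, lens[undecided] - s + 1L)
    mm <- integer(length(undecided))
    for (j in seq_len(alen)) {
      within <- w >= j
      if (!any(within)) break
      mm[within] <- mm[within] +
        (substr(sq[within], s + j - 1L, s + j - 1L) != achars[j])
    }
    hit <- mm <= max_mismatch
    if (any(hit)) {
      pos[undecided[hit]] <- s
      undecided <- undecided[!hit]
      if (!length(undecided)) break
    }
  }
  pos
}

# Number of mismatches between each read prefix and a pattern (pattern
# length w; reads shorter than w count missing positions as mismatches).
.prefix_mismatch <- function(seqs, pattern) {
  w <- nchar(pattern)
  pch <- strsplit(pattern, "")[[1L]]
  mm <- integer(length(seqs))
  for (j in seq_len(w))
    mm <- mm + (substr(seqs, j, j) != pch[j])
  mm
}

#' Assemble a Table-style library accounting record
#'
#' Given the high-quality read count and the five filter categories, the
#' clean-read count is derived from the partition identity
#' \code{high_quality = adapter3_null + insert_null + adapter5_contaminant
#' + shorter_than_18 + polyA + clean_reads}.
#'
#' @param high_quality number of high-quality reads.
#' @param adapter3_null,insert_null,adapter5_contaminant,shorter_than_18,polyA
#'   filter category counts.
#' @param clean_reads optional; when omitted it is derived from the
#'   identity above.
#' @return data.frame of class \code{library_summary} with counts and
#'   percentages of high-quality reads.
#' @export
library_summary <- function(high_quality, adapter3_null, insert_null,
                            adapter5_contaminant, shorter_than_18, polyA,
                            clean_reads = NULL) {
  filtered <- adapter3_null + insert_null + adapter5_contaminant +
    shorter_than_18 + polyA
  if (is.null(clean_reads)) clean_reads <- high_quality - filtered
  if (clean_reads < 0 || filtered + clean_reads != high_quality)
    stop("library summary identity violated: categories must sum to ",
         "high_quality")
  counts <- c(high_quality = high_quality, adapter3_null = adapter3_null,
              insert_null = insert_null,
              adapter5_contaminant = adapter5_contaminant,
              shorter_than_18 = shorter_than_18, polyA = polyA,
              clean_reads = clean_reads)
  pct <- if (high_quality > 0) 100 * counts / high_quality else counts * 0
  out <- data.frame(category = names(counts), count = unname(counts),
                    percent = unname(pct), stringsAsFactors = FALSE)
  class(out) <- c("library_summary", "data.frame")
  out
}

#' Trim adapters and classify reads into filter categories
#'
#' @param reads data.frame with columns \code{id}, \code{seq},
#'   \code{qual} (as from \code{\link{read_fastq}}).
#' @param params a \code{\link{clean_params}} object.
#' @return list with \code{inserts} (data.frame \code{id},
#'   \code{insert} for clean reads, in input order), \code{category}
#'   (factor per read) and \code{summary} (a
#'   \code{\link{library_summary}}).
#' @export
trim_and_filter <- function(reads, params) {
  stopifnot(inherits(params, "clean_params"))
  n <- nrow(reads)
  levs <- c("low_quality", "adapter5_contaminant", "adapter3_null",
            "insert_null", "polyA", "shorter_than_18", "clean")
  category <- factor(rep(NA_character_, n), levels = levs)
  insert <- rep(NA_character_, n)
  if (n > 0L) {
    seqs <- .normalize_seq(reads$seq)
    lens <- nchar(seqs)
    # low quality: any base under min_quality, or too many N
    if (params$min_quality > 0L) {
      qmax <- 33L + params$min_quality - 1L
      pat <- sprintf("[\\x21-\\x%02x]", qmax)
      lowq <- grepl(pat, reads$qual, perl = TRUE)
    } else lowq <- rep(FALSE, n)
    nN <- lens - nchar(gsub("N", "", seqs, fixed = TRUE))
    lowq <- lowq | (nN / pmax(lens, 1L) > params$max_n_frac)
    category[lowq] <- "low_quality"
    todo <- which(!lowq)
    # 5' adapter contaminant
    if (length(todo)) {
      mm5 <- .prefix_mismatch(seqs[todo], params$adapter_5p)
      a5 <- mm5 <= params$adapter_max_mismatch
      category[todo[a5]] <- "adapter5_contaminant"
      todo <- todo[!a5]
    }
    # locate the 3' adapter
    if (length(todo)) {
      pos <- find_adapter(seqs[todo], params$adapter_3p,
                          params$adapter_min_overlap,
                          params$adapter_max_mismatch)
      nohit <- is.na(pos)
      category[todo[nohit]] <- "adapter3_null"
      insnull <- !nohit & pos == 1L
      category[todo[insnull]] <- "insert_null"
      rest <- !nohit & pos > 1L
      ridx <- todo[rest]
      ins <- substr(seqs[ridx], 1L, pos[rest] - 1L)
      ilen <- nchar(ins)
      afrac <- (ilen - nchar(gsub("A", "", ins, fixed = TRUE))) / ilen
      pa <- afrac >= params$polyA_fraction
      category[ridx[pa]] <- "polyA"
      short <- !pa & ilen < params$min_len
      category[ridx[short]] <- "shorter_than_18"
      keep <- !pa & !short
      category[ridx[keep]] <- "clean"
      insert[ridx[keep]] <- ins[keep]
    }
  }
  tab <- table(category)
  summary <- library_summary(
    high_quality = n - as.integer(tab[["low_quality"]]),
    adapter3_null = as.integer(tab[["adapter3_null"]]),
    insert_null = as.integer(tab[["insert_null"]]),
    adapter5_contaminant = as.integer(tab[["adapter5_contaminant"]]),
    shorter_than_18 = as.integer(tab[["shorter_than_18"]]),
    polyA = as.integer(tab[["polyA"]]),
    clean_reads = as.integer(tab[["clean"]]))
  clean_idx <- which(category == "clean")
  list(inserts = data.frame(id = reads$id[clean_idx],
                            insert = insert[clean_idx],
                            stringsAsFactors = FALSE),
       category = category, summary = summary)
}

#' Length distribution of clean tags
#'
#' Histogram of total read counts by insert length over a closed window
#' (default 18--30 nt); lengths outside the window are excluded.
#'
#' @param tags tag data.frame (column \code{sequence} plus count
#'   columns), as from \code{\link{collapse_tags}}.
#' @param range integer length window.
#' @return named integer vector of total read counts per length.
#' @export
length_distribution <- function(tags, range = 18:30) {
  out <- setNames(integer(length(range)), as.character(range))
  if (nrow(tags) == 0L) return(out)
  lens <- nchar(tags$sequence)
  totals <- rowSums(tag_counts(tags))
  keep <- lens %in% range
  if (any(keep)) {
    agg <- tapply(totals[keep], factor(lens[keep], levels = range), sum)
    agg[is.na(agg)] <- 0
    out[] <- as.integer(agg)
  }
  out
}

#' Common and specific tags of two libraries
#'
#' @param tagsA,tagsB tag data.frames with a \code{sequence} column and
#'   count columns (counts are summed per tag).
#' @return list with unique-tag partition sizes (\code{common_unique},
#'   \code{A_specific_unique}, \code{B_specific_unique}) and total read
#'   counts (\code{common_total} sums counts from both libraries over the
#'   shared tags; \code{A_total}/\code{B_total} sum the library-specific
#'   tags).
#' @export
common_specific <- function(tagsA, tagsB) {
  ca <- setNames(rowSums(tag_counts(tagsA)), tagsA$sequence)
  cb <- setNames(rowSums(tag_counts(tagsB)), tagsB$sequence)
  ca <- ca[ca > 0]; cb <- cb[cb > 0]
  common <- intersect(names(ca), names(cb))
  aonly <- setdiff(names(ca), common)
  bonly <- setdiff(names(cb), common)
  list(common_unique = length(common),
       A_specific_unique = length(aonly),
       B_specific_unique = length(bonly),
       common_total = sum(ca[common]) + sum(cb[common]),
       A_total = sum(ca[aonly]),
       B_total = sum(cb[bonly]))
}
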