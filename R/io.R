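# Readers/writers for the on-disk formats shared by all pipeline stages,
# plus the tag-collapsing step.
#
# Conventions: internal coordinates are 0-based half-open; GFF3 emission
# converts to 1-based closed.  Sequences are upper-cased and U is mapped
# to T on input (miRBase mature sequences use U).

.normalize_seq <- function(x) chartr("Uu", "Tt", toupper(x))

#' Read a FASTQ file (Sanger Phred+33)
#'
#' @param path path to a FASTQ file (optionally gzipped).
#' @return data.frame with columns \code{id}, \code{seq}, \code{qual};
#'   records in file order.  Sequences are upper-cased, U converted to T.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  n <- length(lines)
  if (n == 0L)
    return(data.frame(id = character(0), seq = character(0),
                      qual = character(0), stringsAsFactors = FALSE))
  if (n %% 4L != 0L)
    stop("truncated FASTQ record near line ", n, " in ", path)
  hdr <- lines[seq(1L, n, by = 4L)]
  seqs <- .normalize_seq(lines[seq(2L, n, by = 4L)])
  plus <- lines[seq(3L, n, by = 4L)]
  qual <- lines[seq(4L, n, by = 4L)]
  bad <- which(substr(hdr, 1L, 1L) != "@")
  if (length(bad))
    stop("malformed FASTQ header at line ", (bad[1L] - 1L) * 4L + 1L)
  bad <- which(substr(plus, 1L, 1L) != "+")
  if (length(bad))
    stop("malformed FASTQ separator at line ", (bad[1L] - 1L) * 4L + 3L)
  bad <- which(nchar(seqs) != nchar(qual))
  if (length(bad))
    stop("sequence/quality length mismatch at line ",
         (bad[1L] - 1L) * 4L + 2L)
  bad <- which(grepl("[^ACGTN]", seqs))
  if (length(bad))
    stop("non-IUPAC character in sequence at line ",
         (bad[1L] - 1L) * 4L + 2L)
  data.frame(id = sub("^@", "", sub("\\s.*$", "", hdr)),
             seq = seqs, qual = qual, stringsAsFactors = FALSE)
}

#' Write reads as FASTQ
#'
#' @param reads data.frame with columns \code{id}, \code{seq}, \code{qual}.
#' @param path output path (gzipped when it ends in \code{.gz}).
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", reads$qual),
             con)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file path.
#' @return named character vector of upper-case DNA sequences (U mapped
#'   to T).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  out <- .normalize_seq(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                              width = 70L)
  invisible(path)
}

#' Collapse per-read inserts into unique tags with per-library counts
#'
#' One row per distinct sequence; counts are partitioned by library and
#' their grand total equals the number of input inserts.
#'
#' @param library_id character vector of library identifiers, parallel to
#'   \code{insert}.
#' @param insert character vector of clean insert sequences.
#' @param libraries optional character vector fixing the column set and
#'   order (defaults to order of first appearance).
#' @return data.frame with column \code{sequence} followed by one integer
#'   count column per library, rows sorted by sequence.
#' @export
collapse_tags <- function(library_id, insert, libraries = NULL) {
  stopifnot(length(library_id) == length(insert))
  if (is.null(libraries)) libraries <- unique(library_id)
  if (length(insert) == 0L) {
    out <- data.frame(sequence = character(0), stringsAsFactors = FALSE)
    for (l in libraries) out[[l]] <- integer(0)
    return(out)
  }
  stopifnot(all(library_id %in% libraries), all(nzchar(insert)))
  seqs <- sort(unique(insert), method = "radix")
  out <- data.frame(sequence = seqs, stringsAsFactors = FALSE)
  for (l in libraries) {
    tab <- table(factor(insert[library_id == l], levels = seqs))
    out[[l]] <- as.integer(tab)
  }
  out
}

# Count matrix of a tag data.frame (all columns except `sequence`).
tag_counts <- function(tags) {
  m <- as.matrix(tags[, setdiff(names(tags), "sequence"), drop = FALSE])
  rownames(m) <- tags$sequence
  storage.mode(m) <- "integer"
  m
}

#' Write / read a tags-by-libraries count matrix as TSV
#'
#' @param tags data.frame as returned by \code{\link{collapse_tags}} (or
#'   any data.frame whose first column is \code{sequence} or a name
#'   column).
#' @param path TSV path.
#' @return \code{read_counts} returns the data.frame; write returns the
#'   path invisibly.
#' @export
write_counts <- function(tags, path) {
  write.table(tags, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  out <- tryCatch(
    read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
               check.names = FALSE, colClasses = NA),
    error = function(e) stop("malformed count matrix in ", path, ": ",
                             conditionMessage(e)))
  for (cn in setdiff(names(out), names(out)[1L])) {
    if (!is.numeric(out[[cn]]) && nrow(out) > 0L)
      stop("malformed count matrix in ", path, ": non-numeric column ", cn)
    out[[cn]] <- as.integer(out[[cn]])
  }
  if (nrow(out) == 0L) out[[1L]] <- as.character(out[[1L]])
  out
}

#' Write hairpin candidates as GFF3
#'
#' Emits one \code{miRNA_primary_transcript} feature per candidate plus a
#' child \code{miRNA} feature for the mature arm.  Internal 0-based
#' half-open spans are converted to GFF3 1-based closed coordinates.
#'
#' @param candidates data.frame of accepted hairpin candidates (see
#'   \code{\link{find_novel_mirnas}}).
#' @param path output path.
#' @export
write_gff <- function(candidates, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(candidates)) {
    for (i in seq_len(nrow(candidates))) {
      r <- candidates[i, ]
      writeLines(sprintf(
        "%s\tmirflow\tmiRNA_primary_transcript\t%d\t%d\t%.2f\t%s\t.\tID=%s",
        r$contig, r$start + 1L, r$end, r$mfe, r$strand, r$name), con)
      writeLines(sprintf(
        "%s\tmirflow\tmiRNA\t%d\t%d\t.\t%s\t.\tID=%s.mature;Parent=%s",
        r$contig, r$mature_start + 1L, r$mature_end, r$strand,
        r$name, r$name), con)
    }
  }
  invisible(path)
}

#' Write / read a two-column gene-to-term map (TSV)
#'
#' @param map data.frame with columns \code{gene} and \code{term}.
#' @param path TSV path.
#' @export
write_gene_map <- function(map, path) {
  stopifnot(all(c("gene", "term") %in% names(map)))
  write.table(map[, c("gene", "term")], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_map
#' @export
read_gene_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  out <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  if (!all(c("gene", "term") %in% names(out)))
    stop("malformed gene map in ", path,
         ": expected columns 'gene' and 'term'")
  out
}
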