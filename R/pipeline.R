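# End-to-end orchestration: clean -> collapse -> annotate -> novel
# discovery -> differential expression -> target prediction ->
# enrichment, with a run manifest.  Known and novel miRNA counts are
# tested together in the DE stage.

#' Pipeline run configuration
#'
#' @param fastq named character vector of FASTQ paths (names = library
#'   ids).
#' @param groups list with \code{control} and \code{treated} library-id
#'   vectors.
#' @param genome,mature,precursor,transcripts FASTA paths (genome and
#'   transcripts optional: without a genome the novel stage is skipped,
#'   without transcripts the target/enrichment stages are skipped).
#' @param ncrna named character vector of FASTA paths in annotation
#'   priority order (e.g. \code{c(rRNA_gb = ..., rfam = ...)}); each
#'   file may hold one class or, for an Rfam-style file, ids prefixed
#'   \code{class_} which are split into classes.
#' @param gene2go,gene2kegg TSV gene-to-term map paths (optional).
#' @param out_dir output directory.
#' @param clean a \code{\link{clean_params}}.
#' @param tolerance a \code{\link{mirna_tolerance}}.
#' @param criteria a \code{\link{hairpin_criteria}}.
#' @param thresholds a \code{\link{target_thresholds}}.
#' @param alpha DE significance threshold.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(fastq, groups, mature, precursor,
                       genome = NULL, transcripts = NULL,
                       ncrna = character(0), gene2go = NULL,
                       gene2kegg = NULL, out_dir = tempfile("mirflow_run"),
                       clean, tolerance = mirna_tolerance(),
                       criteria = hairpin_criteria(),
                       thresholds = target_thresholds(), alpha = 0.05) {
  cfg <- structure(as.list(environment()), class = "run_config")
  if (is.null(names(cfg$fastq)) || any(!nzchar(names(cfg$fastq))))
    stop("configuration error: fastq paths must be named by library id")
  paths <- c(cfg$fastq, cfg$mature, cfg$precursor, cfg$genome,
             cfg$transcripts, cfg$ncrna, cfg$gene2go, cfg$gene2kegg)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("configuration error: missing input file(s): ",
         paste(missing, collapse = ", "))
  libs <- names(cfg$fastq)
  if (!all(unlist(cfg$groups) %in% libs))
    stop("configuration error: groups name unknown libraries")
  cfg
}

# split an Rfam-style FASTA (ids like "tRNA_1") into per-class sets
.split_ncrna <- function(seqs) {
  cls <- sub("_[^_]*$", "", names(seqs))
  split(seqs, factor(cls, levels = unique(cls)))
}

#' Run the full pipeline
#'
#' Stages run in order; each stage consumes the previous stage's
#' outputs and any failure aborts with the stage name.  A rerun with
#' the same configuration reproduces identical outputs (no stage is
#' stochastic).
#'
#' @param config a \code{\link{run_config}}.
#' @return the run manifest (list): per-stage output paths and the main
#'   result tables (\code{summaries}, \code{tags}, \code{annotation},
#'   \code{novel}, \code{de}, \code{targets}, \code{enrichment}).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  outputs <- character(0)
  emit <- function(obj, file, writer = write_counts) {
    path <- file.path(config$out_dir, file)
    writer(obj, path)
    outputs[[file]] <<- path
    path
  }
  libs <- names(config$fastq)

  ## clean ------------------------------------------------------------
  cleaned <- stage("clean", {
    lapply(setNames(libs, libs), function(lib) {
      trim_and_filter(read_fastq(config$fastq[[lib]]), config$clean)
    })
  })
  summaries <- lapply(cleaned, `[[`, "summary")
  totals <- vapply(summaries, function(s)
    s$count[s$category == "clean_reads"], 0)
  summary_df <- do.call(rbind, lapply(libs, function(l)
    cbind(library = l, summaries[[l]])))
  emit(summary_df, "summary.tsv",
       function(x, p) write.table(x, p, sep = "\t", quote = FALSE,
                                  row.names = FALSE))

  ## collapse ----------------------------------------------------------
  tags <- stage("collapse", {
    collapse_tags(
      rep(libs, vapply(cleaned, function(x) nrow(x$inserts), 0L)),
      unlist(lapply(cleaned, function(x) x$inserts$insert),
             use.names = FALSE),
      libraries = libs)
  })
  emit(tags, "tags.tsv")

  ## annotate ----------------------------------------------------------
  ann <- stage("annotate", {
    ncrna <- list()
    for (nm in names(config$ncrna)) {
      seqs <- read_fasta(config$ncrna[[nm]])
      if (nm %in% c("rfam", "ncrna")) ncrna <- c(ncrna, .split_ncrna(seqs))
      else ncrna[[nm]] <- seqs
    }
    classify_tags(tags, ncrna = ncrna,
                  mature = read_fasta(config$mature),
                  precursor = read_fasta(config$precursor),
                  tolerance = config$tolerance)
  })
  emit(ann$composition, "composition.tsv",
       function(x, p) write.table(x, p, sep = "\t", quote = FALSE,
                                  row.names = FALSE))
  emit(ann$known$hits, "known.tsv",
       function(x, p) write.table(x, p, sep = "\t", quote = FALSE,
                                  row.names = FALSE))

  ## novel -------------------------------------------------------------
  novel <- stage("novel", {
    if (is.null(config$genome)) NULL else {
      un <- ann$assignment$sequence[ann$assignment$category == "unann"]
      find_novel_mirnas(tags[tags$sequence %in% un, , drop = FALSE],
                        read_fasta(config$genome), config$criteria)
    }
  })
  if (!is.null(novel)) {
    emit(novel, "novel.tsv",
         function(x, p) write.table(x, p, sep = "\t", quote = FALSE,
                                    row.names = FALSE))
    emit(novel, "novel.gff3", write_gff)
  }

  ## de ----------------------------------------------------------------
  de <- stage("de", {
    known_counts <- as.matrix(ann$known$hits[, libs, drop = FALSE])
    rownames(known_counts) <- ann$known$hits$name
    counts <- known_counts
    if (!is.null(novel) && nrow(novel)) {
      # one DE row per distinct novel mature sequence
      nv <- novel[!duplicated(novel$mature), , drop = FALSE]
      nv_counts <- as.matrix(nv[, libs, drop = FALSE])
      rownames(nv_counts) <- nv$name
      counts <- rbind(counts, nv_counts)
    }
    de_table(counts, totals, config$groups, alpha = config$alpha)
  })
  emit(de, "de.tsv",
       function(x, p) write.table(x, p, sep = "\t", quote = FALSE,
                                  row.names = FALSE))

  ## targets -----------------------------------------------------------
  targets <- stage("targets", {
    if (is.null(config$transcripts)) NULL else {
      sig <- de$mirna[de$significant]
      seqs <- character(0)
      if (length(sig)) {
        km <- match(sig, ann$known$hits$name)
        seqs <- setNames(ann$known$hits$representative[km], sig)
        if (!is.null(novel) && nrow(novel)) {
          nm <- match(sig, novel$name)
          seqs[!is.na(nm)] <- novel$mature[nm[!is.na(nm)]]
        }
        seqs <- seqs[!is.na(seqs)]
      }
      if (!length(seqs))
        data.frame(mirna = character(0), transcript = character(0),
                   start = integer(0), end = integer(0),
                   site = character(0), penalty = numeric(0),
                   energy = numeric(0), stringsAsFactors = FALSE)
      else scan_targets(seqs, read_fasta(config$transcripts),
                        config$thresholds)
    }
  })
  if (!is.null(targets))
    emit(targets, "targets.tsv",
         function(x, p) write.table(x, p, sep = "\t", quote = FALSE,
                                    row.names = FALSE))

  ## enrich ------------------------------------------------------------
  enrichment <- stage("enrich", {
    if (is.null(targets) || is.null(config$gene2go)) NULL else {
      cand <- unique(targets$transcript)
      go <- enrich_terms(cand, read_gene_map(config$gene2go),
                         method = "bonferroni")
      kegg <- if (is.null(config$gene2kegg)) NULL else
        enrich_terms(cand, read_gene_map(config$gene2kegg),
                     method = "bh_fdr")
      list(go = go, kegg = kegg)
    }
  })
  if (!is.null(enrichment)) {
    emit(enrichment$go, "enrich_go.tsv",
         function(x, p) write.table(x, p, sep = "\t", quote = FALSE,
                                    row.names = FALSE))
    if (!is.null(enrichment$kegg))
      emit(enrichment$kegg, "enrich_kegg.tsv",
           function(x, p) write.table(x, p, sep = "\t", quote = FALSE,
                                      row.names = FALSE))
  }

  manifest <- list(outputs = as.list(outputs),
                   libraries = libs,
                   clean_totals = as.list(totals),
                   n_tags = nrow(tags),
                   n_known = nrow(ann$known$hits),
                   n_novel = if (is.null(novel)) 0L else nrow(novel),
                   n_de_significant = sum(de$significant),
                   n_targets = if (is.null(targets)) 0L else nrow(targets))
  jsonlite::write_json(manifest, file.path(config$out_dir,
                                           "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(manifest,
              list(summaries = summaries, tags = tags, annotation = ann,
                   novel = novel, de = de, targets = targets,
                   enrichment = enrichment)))
}
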