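# Synthetic small RNA corpus generator.
#
# Generates every input the pipeline needs -- genome contigs, a known
# miRNA database (mature + precursor), non-coding RNA references,
# transcripts with planted target sites, gene-to-term maps, and raw
# FASTQ libraries -- together with a ground-truth table.  The stated
# world mirrors the published library structure: 18-30 nt inserts
# flanked by adapters, the five filter-category contaminants at the
# published rates, an rRNA-dominated non-coding background, known
# miRNAs with condition-dependent abundance (planted log2 fold-changes)
# drawn from a negative-binomial count model (dispersion 0 = Poisson),
# genomic hairpin loci emitting novel miRNAs, and transcripts carrying
# planted complementary target sites.
#
# Contaminant and clean inserts are constructed, then validated with
# the cleanse module's own detectors (and resampled on failure), so the
# expected library accounting is exact a priori.

.SIM_LIBS <- c("S1", "S2", "R1", "R2")
.SIM_COND <- c(S1 = "susceptible", S2 = "susceptible",
               R1 = "resistant", R2 = "resistant")

#' Simulation configuration
#'
#' Defaults are the stated world: four libraries (two conditions x two
#' replicates), contamination rates matching the published accounting
#' of the first susceptible library, a ~6\% miRNA fraction of clean
#' reads, five planted differentially expressed miRNAs with |log2 fold
#' change| >= 3, and mild negative-binomial overdispersion.
#'
#' @param seed integer RNG seed; a fixed seed gives byte-identical
#'   output files.
#' @param n_known_mirnas,n_novel_loci,n_transcripts corpus sizes.
#' @param library_depths named integer vector of per-library read
#'   counts (names define the libraries; first half susceptible, second
#'   half resistant).
#' @param contamination_rates named fractions for the five filter
#'   categories (\code{adapter3_null}, \code{insert_null},
#'   \code{adapter5_contaminant}, \code{shorter_than_18}, \code{polyA});
#'   each in [0,1), summing to < 1.
#' @param de_effects named numeric vector: true log2 fold-change
#'   (resistant / susceptible) per mature miRNA name.
#' @param dispersion non-negative negative-binomial dispersion of
#'   per-miRNA counts (0 = Poisson).
#' @param adapter_3p,adapter_5p adapter sequences.
#' @param class_fractions composition of clean reads by class
#'   (\code{mirna}, \code{novel}, \code{ncrna}, \code{unann}).
#' @param read_length raw read length (nt).
#' @param mature_len_range mature miRNA length range (nt).
#' @param abundance_sdlog log-normal sd of per-miRNA base abundance.
#' @param variant_fraction fraction of miRNA reads emitted as +-1 nt
#'   shifted isomiR variants.
#' @param n_unann_pool number of distinct unannotated tag sequences.
#' @param n_go_terms,n_kegg_terms annotation vocabulary sizes.
#' @return validated list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L,
                       n_known_mirnas = 50L,
                       n_novel_loci = 8L,
                       n_transcripts = 30L,
                       library_depths = c(S1 = 20000L, S2 = 20000L,
                                          R1 = 20000L, R2 = 20000L),
                       contamination_rates = c(
                         adapter3_null = 7e-4, insert_null = 2e-4,
                         adapter5_contaminant = 1.9e-3,
                         shorter_than_18 = 0.031, polyA = 5e-6),
                       de_effects = setNames(
                         c(3, 4, 5, -3, -4),
                         paste0("miR-", 1:5, "-5p")),
                       dispersion = 0.05,
                       adapter_3p = "TGGAATTCTCGGGTGCCAAGG",
                       adapter_5p = "GTTCAGAGTTCTACAGTCCGACGATC",
                       class_fractions = c(mirna = 0.06, novel = 0.01,
                                           ncrna = 0.45, unann = 0.48),
                       read_length = 49L,
                       mature_len_range = c(20L, 24L),
                       abundance_sdlog = 1,
                       variant_fraction = 0.1,
                       n_unann_pool = 1000L,
                       n_go_terms = 40L,
                       n_kegg_terms = 15L) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @param config a \code{sim_config} to validate.
#' @export
validate_sim_config <- function(config) {
  err <- function(field, msg)
    stop("configuration error in '", field, "': ", msg, call. = FALSE)
  if (length(config$seed) != 1L || is.na(config$seed))
    err("seed", "must be a single integer")
  for (f in c("n_known_mirnas", "n_novel_loci", "n_transcripts"))
    if (config[[f]] < 0L) err(f, "must be non-negative")
  if (any(config$library_depths <= 0L))
    err("library_depths", "depths must be > 0")
  if (is.null(names(config$library_depths)) ||
      length(config$library_depths) < 2L ||
      length(config$library_depths) %% 2L != 0L)
    err("library_depths", "need a named, even-sized vector")
  cr <- config$contamination_rates
  need <- c("adapter3_null", "insert_null", "adapter5_contaminant",
            "shorter_than_18", "polyA")
  if (!all(need %in% names(cr)))
    err("contamination_rates", paste("must name", paste(need, collapse = ", ")))
  if (any(cr < 0) || any(cr >= 1) || sum(cr) >= 1)
    err("contamination_rates", "fractions must each be in [0,1) and sum < 1")
  if (config$dispersion < 0) err("dispersion", "must be non-negative")
  for (f in c("adapter_3p", "adapter_5p"))
    if (!nzchar(config[[f]]) || grepl("[^ACGT]", config[[f]]))
      err(f, "must be a non-empty A/C/G/T string")
  cf <- config$class_fractions
  if (!all(c("mirna", "novel", "ncrna", "unann") %in% names(cf)) ||
      any(cf < 0) || abs(sum(cf) - 1) > 1e-8)
    err("class_fractions", "must name mirna/novel/ncrna/unann and sum to 1")
  if (config$read_length < 30L) err("read_length", "too short")
  if (config$variant_fraction < 0 || config$variant_fraction > 1)
    err("variant_fraction", "must be in [0,1]")
  if (config$n_unann_pool < 1L && config$class_fractions[["unann"]] > 0)
    err("n_unann_pool", "must be >= 1 when the unann fraction is positive")
  invisible(config)
}

.rand_seq <- function(n, len) {
  len <- rep_len(len, n)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len[i], replace = TRUE),
          collapse = ""), "")
}

# detector-backed validation of a clean insert: the 3' adapter must be
# found exactly at the insert end, the read must not start with the 5'
# adapter, and the polyA filter must not fire
.insert_ok <- function(insert, cp) {
  pos <- find_adapter(paste0(insert, cp$adapter_3p), cp$adapter_3p,
                      cp$adapter_min_overlap, cp$adapter_max_mismatch)
  if (is.na(pos) || pos != nchar(insert) + 1L) return(FALSE)
  if (.prefix_mismatch(insert, cp$adapter_5p) <= cp$adapter_max_mismatch)
    return(FALSE)
  afrac <- (nchar(insert) -
              nchar(gsub("A", "", insert, fixed = TRUE))) / nchar(insert)
  afrac < cp$polyA_fraction
}

.sample_clean_insert <- function(len, cp, max_tries = 200L) {
  for (i in seq_len(max_tries)) {
    s <- .rand_seq(1L, len)
    if (.insert_ok(s, cp)) return(s)
  }
  stop("failed to sample a clean insert")
}

# clean_params implied by a sim_config (the cleanse defaults)
.sim_clean_params <- function(config) {
  clean_params(adapter_3p = config$adapter_3p,
               adapter_5p = config$adapter_5p)
}

# negative-binomial with mean mu and dispersion phi (var = mu + phi mu^2)
.rcounts <- function(n, mu, phi) {
  if (phi <= 0) return(rpois(n, mu))
  rnbinom(n, size = 1 / phi, mu = mu)
}

#' Generate the reference bundle
#'
#' Builds genome contigs with planted novel-miRNA hairpin loci, a known
#' miRNA database, non-coding RNA reference sets, transcripts with
#' planted complementary target sites, gene-to-GO/KEGG maps, and the
#' ground-truth table.  Planted precursors are validated against the
#' hairpin module's own folding and acceptance criteria, so every
#' planted locus is recoverable by construction.
#'
#' @param config a \code{\link{sim_config}}.
#' @param out_dir optional directory; when given, all reference files
#'   are written there (FASTA, TSV maps, BED category intervals, truth
#'   JSON).
#' @return list of class \code{reference_bundle}: \code{genome},
#'   \code{mature}, \code{precursor}, \code{ncrna} (named list),
#'   \code{transcripts}, \code{gene2go}, \code{gene2kegg},
#'   \code{truth}, \code{config}.
#' @export
simulate_reference <- function(config, out_dir = NULL) {
  validate_sim_config(config)
  set.seed(config$seed, kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  cp <- .sim_clean_params(config)
  crit <- hairpin_criteria()
  mlr <- config$mature_len_range

  ## --- known miRNA database ----------------------------------------
  n_known <- config$n_known_mirnas
  mature <- character(0)
  precursor <- character(0)
  if (n_known > 0L) {
    mature <- setNames(character(n_known),
                       paste0("miR-", seq_len(n_known), "-5p"))
    precursor <- setNames(character(n_known),
                          paste0("mir-", seq_len(n_known)))
    for (i in seq_len(n_known)) {
      repeat {
        len <- sample(mlr[1L]:mlr[2L], 1L)
        m <- .rand_seq(1L, len)
        if (!.insert_ok(m, cp)) next
        # shifted isomiR variants must clean correctly too
        flank5 <- .rand_seq(1L, sample(6:12, 1L))
        loop <- .rand_seq(1L, 10L)
        prec <- paste0(flank5, m, loop, revcomp(m), .rand_seq(1L, 4L))
        v1 <- substr(prec, nchar(flank5), nchar(flank5) + len - 1L)
        v2 <- substr(prec, nchar(flank5) + 2L, nchar(flank5) + len + 1L)
        if (.insert_ok(v1, cp) && .insert_ok(v2, cp)) {
          mature[i] <- m
          precursor[i] <- prec
          break
        }
      }
    }
  }
  if (!all(names(config$de_effects) %in% names(mature)))
    stop("configuration error in 'de_effects': unknown miRNA name(s): ",
         paste(setdiff(names(config$de_effects), names(mature)),
               collapse = ", "))

  ## --- genome with planted hairpin loci -----------------------------
  n_contigs <- max(3L, ceiling(config$n_novel_loci / 2L) + 1L)
  contig_len <- 3000L
  genome <- setNames(.rand_seq(n_contigs, contig_len),
                     paste0("contig", seq_len(n_contigs)))
  novel <- list()
  if (config$n_novel_loci > 0L) {
    occupied <- lapply(genome, function(x) NULL)  # planted spans per contig
    for (j in seq_len(config$n_novel_loci)) {
      repeat {
        arm_len <- sample(28:35, 1L)
        mat_len <- sample(mlr[1L]:mlr[2L], 1L)
        mat_off <- sample(3:8, 1L)  # 0-based offset of mature in precursor
        loop_len <- sample(8:12, 1L)
        # the whole precursor downstream of the mature start must fit the
        # 85-nt downstream excision window
        if (2L * arm_len + loop_len + 3L > 82L) next
        arm <- .rand_seq(1L, arm_len)
        loop <- .rand_seq(1L, loop_len)
        # 5' flank keeps the mature within the 15-nt upstream excision
        # window; the 3' flank leaves room for the star's 2-nt overhang
        prec <- paste0(.rand_seq(1L, mat_off), arm, loop, revcomp(arm),
                       .rand_seq(1L, 3L))
        m <- substr(prec, mat_off + 1L, mat_off + mat_len)
        if (!.insert_ok(m, cp)) next
        if (nchar(prec) > crit$max_precursor) next
        fold <- fold_mfe(prec)
        ev <- evaluate_hairpin(prec, m, fold, crit)
        if (!isTRUE(ev$accept)) next
        # plant: overwrite a random contig segment, avoiding (with a
        # margin wide enough for precursor excision) earlier loci
        cn <- sample(names(genome), 1L)
        strand <- sample(c("+", "-"), 1L)
        pstart <- sample(200:(contig_len - nchar(prec) - 200L), 1L)
        span <- c(pstart - 120L, pstart + nchar(prec) + 120L)
        clash <- any(vapply(occupied[[cn]], function(s)
          span[1L] < s[2L] && span[2L] > s[1L], TRUE))
        if (isTRUE(clash)) next
        ins <- if (strand == "+") prec else revcomp(prec)
        genome[[cn]] <- paste0(substr(genome[[cn]], 1L, pstart),
                               ins,
                               substr(genome[[cn]], pstart + nchar(prec) + 1L,
                                      nchar(genome[[cn]])))
        occupied[[cn]] <- c(occupied[[cn]], list(span))
        novel[[j]] <- list(name = sprintf("novel-%02d", j), mature = m,
                           star = ev$star, precursor = prec,
                           contig = cn, strand = strand,
                           start = pstart, end = pstart + nchar(prec),
                           mfe = fold$mfe)
        break
      }
    }
  }

  ## --- non-coding RNA references ------------------------------------
  ncrna <- list(
    rRNA_gb = setNames(.rand_seq(2L, 1200L), paste0("gb_rRNA_", 1:2)),
    rRNA = setNames(.rand_seq(3L, 800L), paste0("rRNA_", 1:3)),
    tRNA = setNames(.rand_seq(5L, 75L), paste0("tRNA_", 1:5)),
    snRNA = setNames(.rand_seq(3L, 150L), paste0("snRNA_", 1:3)),
    snoRNA = setNames(.rand_seq(3L, 120L), paste0("snoRNA_", 1:3)))

  ## --- transcripts with planted target sites ------------------------
  n_tx <- config$n_transcripts
  transcripts <- setNames(.rand_seq(n_tx, 300L + 20L * (seq_len(n_tx) %% 16L)),
                          sprintf("Unigene%04d", seq_len(n_tx)))
  target_truth <- list()
  if (n_tx > 0L && n_known > 0L) {
    planted_mirnas <- names(mature)[seq_len(min(10L, n_known))]
    for (mn in planted_mirnas) {
      ntargets <- sample(1:2, 1L)
      txs <- sample(names(transcripts), ntargets)
      for (tx in txs) {
        site <- revcomp(mature[[mn]])
        L <- nchar(transcripts[[tx]])
        pos <- sample(20:(L - nchar(site) - 20L), 1L)  # 0-based
        transcripts[[tx]] <- paste0(
          substr(transcripts[[tx]], 1L, pos), site,
          substr(transcripts[[tx]], pos + nchar(site) + 1L, L))
        target_truth[[length(target_truth) + 1L]] <-
          data.frame(mirna = paste0("Ofu-", mn), transcript = tx,
                     start = pos, end = pos + nchar(site),
                     stringsAsFactors = FALSE)
      }
    }
  }
  target_truth <- if (length(target_truth))
    do.call(rbind, target_truth) else
      data.frame(mirna = character(0), transcript = character(0),
                 start = integer(0), end = integer(0))

  ## --- gene annotation maps -----------------------------------------
  gene2go <- gene2kegg <- data.frame(gene = character(0),
                                     term = character(0))
  if (n_tx > 0L) {
    gos <- sprintf("GO:%07d", seq_len(config$n_go_terms))
    keggs <- sprintf("ko%05d", seq_len(config$n_kegg_terms))
    g2g <- lapply(names(transcripts), function(g)
      data.frame(gene = g, term = sample(gos, sample(1:5, 1L)),
                 stringsAsFactors = FALSE))
    g2k <- lapply(names(transcripts), function(g)
      data.frame(gene = g, term = sample(keggs, sample(1:3, 1L)),
                 stringsAsFactors = FALSE))
    gene2go <- do.call(rbind, g2g)
    gene2kegg <- do.call(rbind, g2k)
  }

  ## --- per-miRNA abundances and the DE truth ------------------------
  abund <- numeric(0)
  if (n_known > 0L) {
    abund <- setNames(rlnorm(n_known, meanlog = 0,
                             sdlog = config$abundance_sdlog),
                      names(mature))
    # planted DE miRNAs get mid-range base abundance so they stay
    # detectable at moderate depth
    if (length(config$de_effects))
      abund[names(config$de_effects)] <- stats::median(abund) * 2
  }
  lfc <- setNames(rep(0, n_known), names(mature))
  lfc[names(config$de_effects)] <- config$de_effects
  wS <- abund
  wR <- abund * 2^lfc
  truth <- list(
    # susceptible weights sum to 1; resistant weights are deliberately
    # not renormalized so the planted count ratio is exactly 2^lfc
    mirna_weight_susceptible = wS / sum(wS),
    mirna_weight_resistant = (wS / sum(wS)) * 2^lfc,
    mirna_lfc = lfc,
    de_set = names(config$de_effects),
    novel = novel,
    targets = target_truth)

  bundle <- structure(list(genome = genome, mature = mature,
                           precursor = precursor, ncrna = ncrna,
                           transcripts = transcripts,
                           gene2go = gene2go, gene2kegg = gene2kegg,
                           truth = truth, config = config),
                      class = "reference_bundle")
  if (!is.null(out_dir)) write_reference(bundle, out_dir)
  bundle
}

#' Write a reference bundle to disk
#'
#' @param bundle a \code{reference_bundle}.
#' @param out_dir output directory (created if needed).
#' @return named character vector of written paths.
#' @export
write_reference <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genome = file.path(out_dir, "genome.fa"),
             mature = file.path(out_dir, "mature.fa"),
             precursor = file.path(out_dir, "hairpin.fa"),
             genbank = file.path(out_dir, "genbank_rrna.fa"),
             rfam = file.path(out_dir, "rfam.fa"),
             transcripts = file.path(out_dir, "transcripts.fa"),
             gene2go = file.path(out_dir, "gene2go.tsv"),
             gene2kegg = file.path(out_dir, "gene2kegg.tsv"),
             categories = file.path(out_dir, "categories.bed"),
             truth = file.path(out_dir, "truth.json"))
  write_fasta(bundle$genome, paths[["genome"]])
  if (length(bundle$mature)) {
    write_fasta(bundle$mature, paths[["mature"]])
    write_fasta(bundle$precursor, paths[["precursor"]])
  }
  write_fasta(bundle$ncrna$rRNA_gb, paths[["genbank"]])
  rfam <- unlist(lapply(c("rRNA", "tRNA", "snRNA", "snoRNA"),
                        function(cl) bundle$ncrna[[cl]]))
  write_fasta(rfam, paths[["rfam"]])
  if (length(bundle$transcripts))
    write_fasta(bundle$transcripts, paths[["transcripts"]])
  write_gene_map(bundle$gene2go, paths[["gene2go"]])
  write_gene_map(bundle$gene2kegg, paths[["gene2kegg"]])
  bed <- do.call(rbind, lapply(bundle$truth$novel, function(nv)
    data.frame(contig = nv$contig, start = nv$start, end = nv$end,
               name = nv$name, category = "novel_miRNA_locus",
               strand = nv$strand, stringsAsFactors = FALSE)))
  if (is.null(bed))
    bed <- data.frame(contig = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      category = character(0), strand = character(0))
  write.table(bed, paths[["categories"]], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  truth <- bundle$truth
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths
}

# construct one contaminant read of the requested category, validated
# against the cleanse detectors
.make_contaminant <- function(category, cp, read_length, max_tries = 200L) {
  a3 <- cp$adapter_3p; a5 <- cp$adapter_5p
  pad <- function(s) {
    if (nchar(s) >= read_length) return(substr(s, 1L, read_length))
    paste0(s, .rand_seq(1L, read_length - nchar(s)))
  }
  for (i in seq_len(max_tries)) {
    read <- switch(category,
      adapter3_null = .rand_seq(1L, read_length),
      insert_null = pad(a3),
      adapter5_contaminant = pad(paste0(a5, .rand_seq(1L, 21L), a3)),
      shorter_than_18 = pad(paste0(
        .sample_clean_insert(sample(8:17, 1L), cp), a3)),
      polyA = pad(paste0(strrep("A", 21L), a3)),
      stop("unknown contaminant category: ", category))
    got <- .classify_single(read, cp)
    if (got == category) return(read)
  }
  stop("failed to construct a '", category, "' contaminant read")
}

# category of a single structurally-valid read (no quality issues)
.classify_single <- function(read, cp) {
  res <- trim_and_filter(data.frame(id = "x", seq = read,
                                    qual = strrep("I", nchar(read)),
                                    stringsAsFactors = FALSE), cp)
  as.character(res$category[1L])
}

#' Simulate the four FASTQ libraries
#'
#' Draws per-library reads: the five contaminant categories at the
#' configured rates (multinomial), then clean reads split into known
#' miRNA reads (negative-binomial per-miRNA counts with
#' condition-dependent means), novel-locus reads, non-coding RNA
#' fragments and unannotated tags.  Every insert is validated with the
#' cleanse detectors, so the returned expected summaries match the
#' cleanse module's accounting exactly.
#'
#' @param reference a \code{reference_bundle} from
#'   \code{\link{simulate_reference}}.
#' @param config the same \code{\link{sim_config}}.
#' @param out_dir optional directory for FASTQ files and the expected
#'   summary TSV.
#' @return list of class \code{library_set}: \code{reads} (named list
#'   of data.frames id/seq/qual), \code{expected_summary} (named list
#'   of \code{\link{library_summary}}), \code{class_totals} (per-library
#'   reads per annotation class), \code{mirna_counts} and
#'   \code{novel_counts} (true per-library read counts).
#' @export
simulate_libraries <- function(reference, config, out_dir = NULL) {
  stopifnot(inherits(reference, "reference_bundle"))
  validate_sim_config(config)
  if (any(config$library_depths <= 0L)) stop("depth 0 library requested")
  set.seed(config$seed + 1L, kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  cp <- .sim_clean_params(config)
  libs <- names(config$library_depths)
  nlib <- length(libs)
  cond <- setNames(rep(c("susceptible", "resistant"), each = nlib / 2L),
                   libs)
  truth <- reference$truth
  n_known <- length(reference$mature)

  # finite pool of unannotated tags with zipf-like weights
  pool <- character(0)
  if (config$n_unann_pool > 0L) {
    pool <- vapply(seq_len(config$n_unann_pool), function(i)
      .sample_clean_insert(sample(18:30, 1L), cp), "")
    pool_w <- 1 / seq_along(pool)
  }
  # variant table: each known miRNA gets one +-1 shifted isomiR
  variants <- character(n_known)
  if (n_known > 0L) {
    for (i in seq_len(n_known)) {
      m <- reference$mature[[i]]
      prec <- reference$precursor[[i]]
      p <- regexpr(m, prec, fixed = TRUE)
      v <- substr(prec, p + 1L, p + nchar(m))
      variants[i] <- if (.insert_ok(v, cp)) v else m
    }
  }
  nc_classes <- c("rRNA_gb", "rRNA", "tRNA", "snRNA", "snoRNA")
  nc_w <- c(rRNA_gb = 0.35, rRNA = 0.35, tRNA = 0.15, snRNA = 0.08,
            snoRNA = 0.07)
  # pre-draw a pool of validated ncRNA fragments per class
  nc_pool_size <- min(400L, max(25L, as.integer(
    sum(config$library_depths) %/% 25L)))
  nc_pool <- lapply(nc_classes, function(cl) {
    refs <- reference$ncrna[[cl]]
    out <- character(nc_pool_size)
    pri <- match(cl, nc_classes)
    higher <- if (pri > 1L)
      unlist(reference$ncrna[nc_classes[seq_len(pri - 1L)]]) else character(0)
    for (i in seq_along(out)) {
      repeat {
        rs <- refs[[sample(length(refs), 1L)]]
        len <- sample(18:30, 1L)
        st <- sample(nchar(rs) - len, 1L)
        frag <- substr(rs, st + 1L, st + len)
        # must clean correctly and must not also match a
        # higher-priority class (which would shift the composition)
        if (!.insert_ok(frag, cp)) next
        if (length(higher) && !is.na(.substring_ref(frag, higher))) next
        out[i] <- frag
        break
      }
    }
    out
  })
  names(nc_pool) <- nc_classes

  reads <- list()
  expected <- list()
  class_totals <- list()
  mirna_counts <- matrix(0L, n_known, nlib,
                         dimnames = list(names(reference$mature), libs))
  nv_names <- vapply(truth$novel, `[[`, "", "name")
  novel_counts <- matrix(0L, length(truth$novel), nlib,
                         dimnames = list(nv_names, libs))

  cat_names <- c("adapter3_null", "insert_null", "adapter5_contaminant",
                 "shorter_than_18", "polyA")
  for (lib in libs) {
    D <- config$library_depths[[lib]]
    rates <- config$contamination_rates[cat_names]
    draw <- as.integer(rmultinom(1L, D, c(rates, clean = 1 - sum(rates))))
    names(draw) <- c(cat_names, "clean")
    inserts <- character(0)
    # contaminants
    contam_reads <- unlist(lapply(cat_names, function(cat)
      if (draw[[cat]] > 0L)
        vapply(seq_len(draw[[cat]]),
               function(i) .make_contaminant(cat, cp, config$read_length),
               "") else character(0)))
    n_clean <- draw[["clean"]]
    cf <- config$class_fractions
    # per-miRNA counts: NB around the condition means
    w <- if (cond[[lib]] == "susceptible")
      truth$mirna_weight_susceptible else truth$mirna_weight_resistant
    mir_budget <- cf[["mirna"]] * n_clean
    mir_counts <- if (n_known > 0L)
      .rcounts(n_known, mir_budget * w, config$dispersion) else
        integer(0)
    novel_budget <- cf[["novel"]] * n_clean
    nv_counts <- if (length(truth$novel) > 0L)
      .rcounts(length(truth$novel),
               rep(novel_budget / length(truth$novel),
                   length(truth$novel)),
               config$dispersion) else integer(0)
    n_rest <- n_clean - sum(mir_counts) - sum(nv_counts)
    if (n_rest < 0L) {
      # overshoot at tiny depths: trim the miRNA draw deterministically
      over <- -n_rest
      while (over > 0L) {
        i <- which.max(mir_counts)
        cut <- min(over, mir_counts[i])
        mir_counts[i] <- mir_counts[i] - cut
        over <- over - cut
      }
      n_rest <- 0L
    }
    n_nc <- min(n_rest, as.integer(round(
      n_rest * cf[["ncrna"]] / (cf[["ncrna"]] + cf[["unann"]]))))
    n_un <- n_rest - n_nc
    # assemble clean inserts
    mir_inserts <- character(0)
    if (n_known > 0L && sum(mir_counts) > 0L) {
      idx <- rep(seq_len(n_known), mir_counts)
      use_var <- runif(length(idx)) < config$variant_fraction
      mir_inserts <- ifelse(use_var, variants[idx],
                            unname(reference$mature[idx]))
      mirna_counts[, lib] <- as.integer(mir_counts)
    }
    nv_inserts <- character(0)
    if (length(truth$novel) && sum(nv_counts) > 0L) {
      idx <- rep(seq_along(truth$novel), nv_counts)
      nv_inserts <- vapply(truth$novel[idx], `[[`, "", "mature")
      novel_counts[, lib] <- as.integer(nv_counts)
    }
    nc_inserts <- character(0)
    nc_class_draw <- integer(0)
    if (n_nc > 0L) {
      nc_class_draw <- sample(nc_classes, n_nc, replace = TRUE,
                              prob = nc_w[nc_classes])
      nc_inserts <- vapply(nc_class_draw, function(cl)
        nc_pool[[cl]][sample(length(nc_pool[[cl]]), 1L)], "")
    }
    un_inserts <- character(0)
    if (n_un > 0L && length(pool))
      un_inserts <- pool[sample(length(pool), n_un, replace = TRUE,
                                prob = pool_w)]
    clean_inserts <- c(mir_inserts, nv_inserts, nc_inserts, un_inserts)
    clean_reads <- vapply(clean_inserts, function(s) {
      r <- paste0(s, config$adapter_3p)
      if (nchar(r) >= config$read_length)
        substr(r, 1L, config$read_length) else
          paste0(r, .rand_seq(1L, config$read_length - nchar(r)))
    }, "", USE.NAMES = FALSE)
    all_reads <- c(contam_reads, clean_reads)
    ord <- sample(length(all_reads))
    df <- data.frame(
      id = sprintf("%s_r%07d", lib, seq_along(all_reads)),
      seq = all_reads[ord],
      qual = strrep("I", nchar(all_reads[ord])),
      stringsAsFactors = FALSE)
    reads[[lib]] <- df
    expected[[lib]] <- library_summary(
      high_quality = length(all_reads),
      adapter3_null = draw[["adapter3_null"]],
      insert_null = draw[["insert_null"]],
      adapter5_contaminant = draw[["adapter5_contaminant"]],
      shorter_than_18 = draw[["shorter_than_18"]],
      polyA = draw[["polyA"]],
      clean_reads = length(clean_inserts))
    class_totals[[lib]] <- c(
      known_miRNA = length(mir_inserts), novel = length(nv_inserts),
      table(factor(nc_class_draw, levels = nc_classes)),
      unann_pool = length(un_inserts))
  }
  out <- structure(list(reads = reads, expected_summary = expected,
                        class_totals = class_totals,
                        mirna_counts = mirna_counts,
                        novel_counts = novel_counts,
                        conditions = cond),
                   class = "library_set")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (lib in libs)
      write_fastq(reads[[lib]], file.path(out_dir,
                                          paste0(lib, ".fastq")))
    exp_df <- do.call(rbind, lapply(libs, function(l)
      cbind(library = l, expected[[l]])))
    write.table(exp_df, file.path(out_dir, "expected_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Simulate a complete corpus (reference + libraries)
#'
#' @param config a \code{\link{sim_config}}.
#' @param out_dir optional output directory; reference files are
#'   written under \code{out_dir/reference}, FASTQ under
#'   \code{out_dir/reads}.
#' @return list with \code{reference} and \code{libraries}.
#' @export
simulate_corpus <- function(config, out_dir = NULL) {
  ref_dir <- if (is.null(out_dir)) NULL else file.path(out_dir, "reference")
  reads_dir <- if (is.null(out_dir)) NULL else file.path(out_dir, "reads")
  reference <- simulate_reference(config, ref_dir)
  libraries <- simulate_libraries(reference, config, reads_dir)
  invisible(list(reference = reference, libraries = libraries))
}
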