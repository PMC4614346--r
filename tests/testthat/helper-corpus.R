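# Shared synthetic corpus fixture, built once per test run and cached.
# Small enough to keep the default suite fast, large enough that every
# pipeline stage produces non-trivial output.

.corpus_cache <- new.env(parent = emptyenv())

small_sim_config <- function(seed = 7L) {
  sim_config(seed = seed, n_known_mirnas = 20L, n_novel_loci = 4L,
             n_transcripts = 15L,
             library_depths = c(S1 = 4000L, S2 = 4000L,
                                R1 = 4000L, R2 = 4000L),
             de_effects = setNames(c(3, -4), c("miR-1-5p", "miR-2-5p")),
             n_unann_pool = 300L)
}

# corpus + written files + a full pipeline run, memoized
small_corpus_run <- function() {
  if (!is.null(.corpus_cache$run)) return(.corpus_cache$run)
  cfg <- small_sim_config()
  out <- file.path(tempdir(), "mirflow-test-corpus")
  corpus <- simulate_corpus(cfg, out)
  libs <- names(cfg$library_depths)
  rc <- run_config(
    fastq = setNames(file.path(out, "reads", paste0(libs, ".fastq")),
                     libs),
    groups = list(control = c("S1", "S2"), treated = c("R1", "R2")),
    mature = file.path(out, "reference", "mature.fa"),
    precursor = file.path(out, "reference", "hairpin.fa"),
    genome = file.path(out, "reference", "genome.fa"),
    transcripts = file.path(out, "reference", "transcripts.fa"),
    ncrna = c(rRNA_gb = file.path(out, "reference", "genbank_rrna.fa"),
              rfam = file.path(out, "reference", "rfam.fa")),
    gene2go = file.path(out, "reference", "gene2go.tsv"),
    gene2kegg = file.path(out, "reference", "gene2kegg.tsv"),
    clean = clean_params(cfg$adapter_3p, cfg$adapter_5p),
    out_dir = file.path(tempdir(), "mirflow-test-run"))
  res <- run_pipeline(rc)
  .corpus_cache$run <- list(cfg = cfg, out = out, corpus = corpus,
                            rc = rc, res = res)
  .corpus_cache$run
}

# default adapters used by hand-built cleaning fixtures
A3 <- "TGGAATTCTCGGGTGCCAAGG"
A5 <- "GTTCAGAGTTCTACAGTCCGACGATC"

make_reads <- function(seqs, qual = NULL) {
  if (is.null(qual)) qual <- strrep("I", nchar(seqs))
  data.frame(id = paste0("r", seq_along(seqs)), seq = seqs, qual = qual,
             stringsAsFactors = FALSE)
}
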