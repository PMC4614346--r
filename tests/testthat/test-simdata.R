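# Synthetic corpus generator: determinism, stated-world structure and
# count model

test_that("configuration errors name the offending field", {
  expect_error(sim_config(library_depths = c(S1 = 0L, R1 = 10L)),
               "library_depths")
  expect_error(sim_config(contamination_rates = c(
    adapter3_null = 0.5, insert_null = 0.4, adapter5_contaminant = 0.2,
    shorter_than_18 = 0, polyA = 0)), "contamination_rates")
  expect_error(sim_config(dispersion = -1), "dispersion")
  expect_error(sim_config(class_fractions = c(mirna = 1, novel = 1,
                                              ncrna = 0, unann = 0)),
               "class_fractions")
  expect_error(sim_config(adapter_3p = "ACGTN"), "adapter_3p")
  cfg <- sim_config(de_effects = c("miR-999-5p" = 3))
  expect_error(simulate_reference(cfg), "de_effects")
})

test_that("a fixed seed reproduces byte-identical output files", {
  cfg <- sim_config(seed = 5L, n_known_mirnas = 5L, n_novel_loci = 1L,
                    n_transcripts = 4L,
                    library_depths = c(S1 = 300L, R1 = 300L),
                    de_effects = setNames(numeric(0), character(0)),
                    n_unann_pool = 50L)
  d1 <- file.path(tempdir(), "simrep1")
  d2 <- file.path(tempdir(), "simrep2")
  unlink(c(d1, d2), recursive = TRUE)
  simulate_corpus(cfg, d1)
  simulate_corpus(cfg, d2)
  files <- list.files(d1, recursive = TRUE)
  expect_gt(length(files), 5L)
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
})

test_that("zero novel loci gives an empty truth set and no planted hairpins", {
  cfg <- sim_config(seed = 2L, n_known_mirnas = 3L, n_novel_loci = 0L,
                    n_transcripts = 2L,
                    library_depths = c(S1 = 200L, R1 = 200L),
                    de_effects = setNames(numeric(0), character(0)),
                    n_unann_pool = 30L)
  ref <- simulate_reference(cfg)
  expect_equal(length(ref$truth$novel), 0L)
})

test_that("mature lengths, precursor descriptors and planted structures hold", {
  run <- small_corpus_run()
  ref <- run$corpus$reference
  expect_true(all(nchar(ref$mature) >= 20 & nchar(ref$mature) <= 24))
  for (nv in ref$truth$novel) {
    expect_true(nchar(nv$mature) >= 20 && nchar(nv$mature) <= 24)
    expect_true(nchar(nv$precursor) >= 60 &&
                  nchar(nv$precursor) <= 100)
    # planted mature is a substring of its precursor and locus
    expect_true(grepl(nv$mature, nv$precursor, fixed = TRUE))
    locus_seq <- substr(ref$genome[[nv$contig]], nv$start + 1L, nv$end)
    if (nv$strand == "-") locus_seq <- revcomp(locus_seq)
    expect_identical(locus_seq, nv$precursor)
    # folds below the acceptance threshold under the package energy model
    expect_lte(fold_mfe(nv$precursor)$mfe, -18)
  }
  # planted target sites are exact reverse complements at their spans
  truth <- ref$truth$targets
  mat <- setNames(unname(ref$mature), paste0("Ofu-", names(ref$mature)))
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    site <- substr(ref$transcripts[[tr$transcript]], tr$start + 1L,
                   tr$end)
    expect_identical(site, revcomp(mat[[tr$mirna]]))
  }
})

test_that("expected summaries match the cleanse accounting exactly", {
  run <- small_corpus_run()
  cp <- clean_params(run$cfg$adapter_3p, run$cfg$adapter_5p)
  for (lib in names(run$corpus$libraries$reads)) {
    obs <- trim_and_filter(run$corpus$libraries$reads[[lib]], cp)$summary
    exp <- run$corpus$libraries$expected_summary[[lib]]
    expect_equal(obs$count, exp$count, label = lib)
  }
})

test_that("contamination draws follow the configured binomial rates", {
  cfg <- sim_config(seed = 17L, n_known_mirnas = 3L, n_novel_loci = 0L,
                    n_transcripts = 2L,
                    library_depths = c(S1 = 10000L, R1 = 100L),
                    contamination_rates = c(
                      adapter3_null = 0, insert_null = 0,
                      adapter5_contaminant = 0, shorter_than_18 = 0,
                      polyA = 0.01),
                    de_effects = setNames(numeric(0), character(0)),
                    n_unann_pool = 50L)
  corpus <- simulate_corpus(cfg)
  s <- corpus$libraries$expected_summary$S1
  polyA <- s$count[s$category == "polyA"]
  # binomial: mean 100, sd ~ 10; allow 4.5 sd
  expect_gt(polyA, 55)
  expect_lt(polyA, 145)
  expect_equal(s$count[s$category %in%
                         c("adapter3_null", "insert_null",
                           "adapter5_contaminant", "shorter_than_18")],
               rep(0, 4))
})

test_that("all-zero contamination makes clean reads equal high-quality", {
  cfg <- sim_config(seed = 13L, n_known_mirnas = 3L, n_novel_loci = 0L,
                    n_transcripts = 2L,
                    library_depths = c(S1 = 500L, R1 = 500L),
                    contamination_rates = c(
                      adapter3_null = 0, insert_null = 0,
                      adapter5_contaminant = 0, shorter_than_18 = 0,
                      polyA = 0),
                    de_effects = setNames(numeric(0), character(0)),
                    n_unann_pool = 50L)
  corpus <- simulate_corpus(cfg)
  for (s in corpus$libraries$expected_summary)
    expect_equal(s$count[s$category == "clean_reads"],
                 s$count[s$category == "high_quality"])
})

test_that("a planted +3 lfc doubles count means eightfold (Poisson limit)", {
  cfg <- sim_config(seed = 29L, n_known_mirnas = 20L, n_novel_loci = 0L,
                    n_transcripts = 2L,
                    library_depths = c(S1 = 100000L, S2 = 100000L,
                                       R1 = 100000L, R2 = 100000L),
                    de_effects = c("miR-1-5p" = 3),
                    dispersion = 0,
                    n_unann_pool = 100L)
  corpus <- simulate_corpus(cfg)
  cm <- corpus$libraries$mirna_counts["miR-1-5p", ]
  ratio <- sum(cm[c("R1", "R2")]) / sum(cm[c("S1", "S2")])
  expect_lt(abs(ratio / 8 - 1), 0.1)
})
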