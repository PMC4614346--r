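# Read-cleaning cascade and library accounting

cp <- clean_params(A3, A5)

test_that("clean_params validates its inputs", {
  expect_error(clean_params("", A5), "adapter_3p")
  expect_error(clean_params(A3, ""), "adapter_5p")
  expect_error(clean_params(A3, A5, min_len = 30, max_len = 18),
               "min_len")
  expect_error(clean_params(A3, A5, polyA_fraction = 0), "polyA")
  expect_error(clean_params("ACGTAC", A5, adapter_min_overlap = 10),
               "adapter_min_overlap")
})

test_that("reads are assigned to categories in priority order", {
  insert <- "ACATGACTTGAACATGACAGT"  # 21 nt, moderate A content
  reads <- make_reads(c(
    paste0(insert, A3, "TTTTTTT"),          # clean
    paste0(A3, "ACGTACGTACGTACGTACGTACGTACG"), # insert-null
    paste0(strrep("A", 21), A3, "TTTTTTT"), # polyA
    paste0("ACGTACGTAC", A3),               # shorter than 18
    strrep("ACGT", 12),                     # no 3' adapter
    paste0(A5, "ACATGACTTGAACATGACAGT", A3) # 5' contaminant
  ))
  res <- trim_and_filter(reads, cp)
  expect_equal(as.character(res$category),
               c("clean", "insert_null", "polyA", "shorter_than_18",
                 "adapter3_null", "adapter5_contaminant"))
  expect_equal(res$inserts$insert, insert)
  s <- res$summary
  expect_equal(s$count[s$category == "high_quality"], 6)
  expect_equal(s$count[s$category == "clean_reads"], 1)
})

test_that("low-quality reads are excluded from the high-quality total", {
  reads <- make_reads(c("ACGTACGTACGTACGTACGTA", "ACGTACGTACGTACGTACGTA"),
                      qual = c(strrep("I", 21),
                               paste0("!", strrep("I", 20))))
  res <- trim_and_filter(reads, cp)
  expect_equal(as.character(res$category)[2], "low_quality")
  expect_equal(res$summary$count[res$summary$category == "high_quality"],
               1)
  # many-N reads are low quality as well
  reads <- make_reads("ACGNNNNNACGTACGTACGTA")
  res <- trim_and_filter(reads, cp)
  expect_equal(as.character(res$category), "low_quality")
})

test_that("adapter matching honours overlap and mismatch settings", {
  insert <- "CTGACATGACTTGACATGACA"
  # adapter with one mismatch still found
  mm_adapter <- paste0("A", substr(A3, 2, nchar(A3)))
  reads <- make_reads(paste0(insert, mm_adapter))
  res <- trim_and_filter(reads, cp)
  expect_equal(res$inserts$insert, insert)
  # adapter truncated at the read end: prefix overlap >= 6 suffices
  reads <- make_reads(paste0(insert, substr(A3, 1, 7)))
  res <- trim_and_filter(reads, cp)
  expect_equal(res$inserts$insert, insert)
  # 5-nt terminal fragment is not a match
  reads <- make_reads(paste0(insert, substr(A3, 1, 5)))
  res <- trim_and_filter(reads, cp)
  expect_equal(as.character(res$category), "adapter3_null")
})

test_that("the published accounting column reproduces its clean reads", {
  s <- library_summary(high_quality = 5964851, adapter3_null = 4147,
                       insert_null = 1228, adapter5_contaminant = 11222,
                       shorter_than_18 = 184717, polyA = 28)
  expect_identical(s$count[s$category == "clean_reads"], 5763509)
  expect_equal(s$percent[s$category == "clean_reads"], 96.62, tolerance = 1e-4)
  expect_error(library_summary(100, 10, 10, 10, 10, 10,
                               clean_reads = 99),
               "identity")
})

test_that("category counts satisfy the accounting identity on random corpora", {
  for (seed in 1:5) {
    cfg <- sim_config(seed = seed, n_known_mirnas = 5L,
                      n_novel_loci = 0L, n_transcripts = 2L,
                      library_depths = c(S1 = 300L, R1 = 300L),
                      de_effects = setNames(numeric(0), character(0)),
                      n_unann_pool = 50L)
    corpus <- simulate_corpus(cfg)
    for (lib in names(corpus$libraries$reads)) {
      res <- trim_and_filter(corpus$libraries$reads[[lib]],
                             clean_params(cfg$adapter_3p, cfg$adapter_5p))
      s <- res$summary
      cats <- s$count[s$category != "high_quality"]
      expect_equal(sum(cats), s$count[s$category == "high_quality"])
    }
  }
})

test_that("length_distribution bins total reads by insert length", {
  tags <- collapse_tags(rep("L1", 5), rep(rand_nt(21), 5))
  h <- length_distribution(tags)
  expect_equal(unname(h[["21"]]), 5L)
  expect_equal(sum(h), 5L)
  # empty input -> all-zero histogram
  empty <- collapse_tags(character(0), character(0), libraries = "L1")
  expect_true(all(length_distribution(empty) == 0L))
  # out-of-range lengths excluded
  tags <- collapse_tags(c("L1", "L1"), c(rand_nt(17), rand_nt(31)))
  expect_equal(sum(length_distribution(tags)), 0L)
})

test_that("common_specific partitions tags and totals correctly", {
  tA <- collapse_tags(rep("A", 2), c("AA", "AA"))
  tB <- collapse_tags(rep("B", 4), c("AA", "AA", "AA", "AC"))
  cs <- common_specific(tA, tB)
  expect_equal(cs$common_unique, 1L)
  expect_equal(cs$common_total, 5)
  expect_equal(cs$B_specific_unique, 1L)
  expect_equal(cs$B_total, 1)
  expect_equal(cs$A_specific_unique, 0L)
  # identical sets -> no specific tags; disjoint -> no common
  cs <- common_specific(tA, tA)
  expect_equal(cs$A_specific_unique + cs$B_specific_unique, 0L)
  tC <- collapse_tags("C", "GG")
  cs <- common_specific(tA, tC)
  expect_equal(cs$common_unique, 0L)
})
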