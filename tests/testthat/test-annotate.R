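# Tag annotation: priority rule and known-miRNA identification

mk_tags <- function(seqs, counts = rep(1L, length(seqs))) {
  collapse_tags(rep("L1", sum(counts)), rep(seqs, counts))
}

test_that("the priority rule assigns a multi-category tag to rRNA", {
  mat <- c("miR-9-3p" = "ACGTGACCTGAAGTAGCGCA")
  prec <- c("mir-9" = paste0("GGTTGG", mat, "CCAACCAAGG",
                             revcomp(mat)))
  # the rRNA reference contains the mature sequence verbatim
  rrna <- c(rRNA_1 = paste0("TTTTT", mat, "GGGGGAAACCCTTT"))
  tags <- mk_tags(unname(mat))
  res <- classify_tags(tags, ncrna = list(rRNA = rrna),
                       mature = mat, precursor = prec)
  expect_equal(res$assignment$category, "rRNA")
  expect_equal(nrow(res$known$hits), 0L)
})

test_that("unmatched tags fall through to unann", {
  tags <- mk_tags("TTACGGTTACGGTTACGGTT")
  res <- classify_tags(tags, ncrna = list(rRNA = c(r1 = rand_nt(200))),
                       mature = c("miR-1-5p" = rand_nt(22)),
                       precursor = character(0))
  expect_equal(res$assignment$category, "unann")
})

test_that("exact mature matches are named with the species prefix", {
  mat <- c("miR-1-3p" = "TGGAATGTAAAGAAGTATGGAG")
  res <- match_known_mirnas(mk_tags(unname(mat)), mat)
  expect_equal(res$hits$name, "Ofu-miR-1-3p")
  expect_equal(res$hits$representative, unname(mat))
})

test_that("a +3 nt shifted tag is not matched under the +-2 tolerance", {
  mat <- c("miR-2-5p" = "CATCGTACCGGGTACACTCAGT")
  prec <- c("mir-2" = paste0("AACCGGTT", mat, "GGAACCTT",
                             revcomp(mat), "AA"))
  shifted <- substr(prec, 8L + 4L, 8L + 3L + nchar(mat))  # +3 shift
  res <- match_known_mirnas(mk_tags(shifted), mat, prec)
  expect_equal(nrow(res$hits), 0L)
  # +2 shift is matched
  shifted2 <- substr(prec, 8L + 3L, 8L + 2L + nchar(mat))
  res <- match_known_mirnas(mk_tags(shifted2), mat, prec)
  expect_equal(res$hits$reference, "miR-2-5p")
})

test_that("mismatch tolerance accepts <=2 and rejects 3 mismatches", {
  mat <- c("miR-3-5p" = "ACGTGACCTGAAGTAGCGCA")
  s <- strsplit(unname(mat), "")[[1]]
  s[5] <- setdiff(c("A", "C", "G", "T"), s[5])[1]
  s[10] <- setdiff(c("A", "C", "G", "T"), s[10])[1]
  mm2 <- paste(s, collapse = "")
  s[15] <- setdiff(c("A", "C", "G", "T"), s[15])[1]
  mm3 <- paste(s, collapse = "")
  res <- match_known_mirnas(mk_tags(mm2), mat)
  expect_equal(res$hits$reference, "miR-3-5p")
  expect_equal(res$tag_map$mismatches, 2L)
  res <- match_known_mirnas(mk_tags(mm3), mat)
  expect_equal(nrow(res$hits), 0L)
})

test_that("variants of one reference pool under one hit", {
  mat <- c("miR-4-5p" = "GTCCGATTGACCGGACTTGA")
  prec <- c("mir-4" = paste0("CCAATTGG", mat, "CTTCAATCGG",
                             revcomp(mat), "TT"))
  v1 <- unname(mat)
  v2 <- substr(prec, 10, 9 + nchar(mat))  # +1 shifted variant
  tags <- collapse_tags(rep("L1", 10), c(rep(v1, 7), rep(v2, 3)))
  res <- match_known_mirnas(tags, mat, prec)
  expect_equal(nrow(res$hits), 1L)
  expect_equal(res$hits$L1, 10L)
  expect_equal(res$hits$n_variants, 2L)
  expect_equal(res$hits$representative, v1)  # the higher-count variant
})

test_that("categories partition the unique tags", {
  run <- small_corpus_run()
  comp <- run$res$annotation$composition
  expect_equal(sum(comp$unique), nrow(run$res$tags))
  # per-library totals also partition the clean reads
  for (lib in c("S1", "S2", "R1", "R2"))
    expect_equal(sum(comp[[lib]]), run$res$clean_totals[[lib]])
})

test_that("on synthetic data the composition matches the generator truth", {
  run <- small_corpus_run()
  comp <- run$res$annotation$composition
  ct <- run$corpus$libraries$class_totals
  for (lib in c("S1", "S2", "R1", "R2")) {
    truth <- ct[[lib]]
    expect_equal(comp[[lib]][comp$category == "known_miRNA"],
                 unname(truth[["known_miRNA"]]))
    for (cl in c("rRNA_gb", "rRNA", "tRNA", "snRNA", "snoRNA"))
      expect_equal(comp[[lib]][comp$category == cl],
                   unname(truth[[cl]]), label = paste(lib, cl))
    # novel matures are unannotated at this stage
    expect_equal(comp[[lib]][comp$category == "unann"],
                 unname(truth[["unann_pool"]] + truth[["novel"]]))
  }
})

test_that("every planted known miRNA with reads is recovered", {
  run <- small_corpus_run()
  truth_counts <- run$corpus$libraries$mirna_counts
  expressed <- rownames(truth_counts)[rowSums(truth_counts) > 0]
  hits <- run$res$annotation$known$hits
  expect_true(all(paste0("Ofu-", expressed) %in% hits$name))
  # pooled counts match the generator truth (variants pooled back)
  for (mi in expressed) {
    row <- hits[hits$reference == mi, ]
    expect_equal(unlist(row[, c("S1", "S2", "R1", "R2")]),
                 truth_counts[mi, ], ignore_attr = TRUE)
  }
})
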