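# MFE folding and novel miRNA discovery

test_that("unpairable sequences fold into the empty structure", {
  f <- fold_mfe("AAAAAAAAAA")
  expect_equal(f$structure, "..........")
  expect_equal(f$mfe, 0)
  expect_true(all(f$pairs == 0L))
  expect_error(fold_mfe("ACGTN"), "non-nucleotide")
})

test_that("the DP matches exhaustive enumeration on short sequences", {
  expect_equal(fold_mfe("GGGGAAAACCCC")$mfe,
               brute_force_mfe("GGGGAAAACCCC"))
  set.seed(19)
  for (i in 1:25) {
    s <- rand_nt(sample(8:16, 1), c("A", "C", "G", "U"))
    expect_equal(fold_mfe(s)$mfe, brute_force_mfe(s), tolerance = 1e-9,
                 label = s)
  }
})

test_that("folded structures are well-formed and re-scorable", {
  set.seed(23)
  for (i in 1:10) {
    s <- rand_nt(60)
    f <- fold_mfe(s)
    # balanced brackets, consistent partner vector
    expect_equal(sum(f$pairs > 0), 2 * lengths(regmatches(
      f$structure, gregexpr("(", f$structure, fixed = TRUE))))
    paired <- which(f$pairs > 0)
    expect_true(all(f$pairs[f$pairs[paired]] == paired))
    # no loop shorter than 3
    opens <- which(f$pairs > seq_along(f$pairs))
    expect_true(all(f$pairs[opens] - opens > 3))
    # the traceback structure reproduces the reported energy
    expect_equal(mirflow:::structure_energy(
      mirflow:::seq_to_codes(s), f$pairs), f$mfe, tolerance = 1e-9)
  }
})

test_that("map_unannotated reports all exact placements on both strands", {
  genome <- c(c1 = paste0(rand_nt(50), "ACGTGACCTGAAGTAGCGCAT",
                          rand_nt(50)))
  tag <- "ACGTGACCTGAAGTAGCGCAT"
  pl <- map_unannotated(tag, genome)
  expect_equal(nrow(pl), 1L)
  expect_equal(pl$strand, "+")
  expect_equal(pl$start, 50L)
  expect_equal(pl$end, 71L)
  # reverse-complement tag maps on the minus strand at the same locus
  pl <- map_unannotated(revcomp(tag), genome)
  expect_equal(pl$strand, "-")
  expect_equal(pl$start, 50L)
  # multi-locus tags give one placement per locus
  g4 <- c(c1 = paste0(rand_nt(30), tag, rand_nt(30), tag, rand_nt(30)),
          c2 = paste0(rand_nt(30), tag, rand_nt(30), tag, rand_nt(30)))
  expect_equal(nrow(map_unannotated(tag, g4)), 4L)
})

test_that("extract_precursors returns clipped windows containing the tag", {
  set.seed(5)
  genome <- c(c1 = rand_nt(400))
  tag <- substr(genome, 201, 221)
  pl <- data.frame(tag = tag, contig = "c1", strand = "+",
                   start = 200L, end = 221L, stringsAsFactors = FALSE)
  cands <- extract_precursors(pl, genome)
  expect_equal(nrow(cands), 2L)
  expect_equal(nchar(cands$seq), c(100L, 100L))
  expect_true(all(grepl(tag, cands$seq, fixed = TRUE)))
  # tag at the contig start: clipped but still contains the tag
  tag2 <- substr(genome, 1, 21)
  pl2 <- data.frame(tag = tag2, contig = "c1", strand = "+",
                    start = 0L, end = 21L, stringsAsFactors = FALSE)
  cands2 <- extract_precursors(pl2, genome)
  expect_true(all(grepl(tag2, cands2$seq, fixed = TRUE)))
  expect_true(any(nchar(cands2$seq) < 100L))
})

test_that("evaluate_hairpin rejects by mfe and mature length", {
  # a clean planted hairpin from the generator truth
  run <- small_corpus_run()
  nv <- run$corpus$reference$truth$novel[[1]]
  fold <- fold_mfe(nv$precursor)
  ev <- evaluate_hairpin(nv$precursor, nv$mature, fold)
  expect_true(ev$accept)
  expect_equal(ev$arm, "5p")
  # an under-threshold mfe is rejected with reason "mfe"
  weak <- hairpin_criteria(max_mfe = -1000)
  ev <- evaluate_hairpin(nv$precursor, nv$mature, fold, weak)
  expect_equal(ev$reason, "mfe")
  # mature length outside [20, 24] is rejected with reason "length"
  short_tag <- substr(nv$mature, 1, 19)
  ev <- evaluate_hairpin(nv$precursor, short_tag, fold)
  expect_equal(ev$reason, "length")
})

test_that("accepted candidates satisfy every criterion post hoc", {
  run <- small_corpus_run()
  novel <- run$res$novel
  expect_gt(nrow(novel), 0L)
  crit <- hairpin_criteria()
  for (i in seq_len(nrow(novel))) {
    r <- novel[i, ]
    expect_lte(r$mfe, crit$max_mfe)
    expect_gte(r$mature_len, crit$mature_len[1])
    expect_lte(r$mature_len, crit$mature_len[2])
    expect_true(grepl(r$mature, r$seq, fixed = TRUE))
    expect_equal(nchar(r$structure), nchar(r$seq))
    # re-fold and re-evaluate from scratch
    ev <- evaluate_hairpin(r$seq, r$mature, fold_mfe(r$seq), crit)
    expect_true(ev$accept)
  }
})

test_that("planted loci are recovered on synthetic data", {
  run <- small_corpus_run()
  truth <- run$corpus$reference$truth$novel
  novel <- run$res$novel
  counts <- run$corpus$libraries$novel_counts
  for (k in seq_along(truth)) {
    nv <- truth[[k]]
    if (sum(counts[nv$name, ]) < 10) next
    hit <- novel[novel$contig == nv$contig &
                   novel$start < nv$end & novel$end > nv$start, ]
    expect_gte(nrow(hit), 1L)
    # the recovered mature is the planted tag (possibly at both arms)
    expect_true(nv$mature %in% hit$mature)
  }
})

test_that("name_candidates numbers sequentially and keeps multi-locus records", {
  acc <- data.frame(
    mature = rep("ACGTGACCTGAAGTAGCGCA", 2),
    seq = rep("CCC", 2), contig = c("c1", "c2"), strand = "+",
    start = c(10L, 400L), end = c(90L, 480L), arm = c("5p", "3p"),
    stringsAsFactors = FALSE)
  named <- name_candidates(acc)
  expect_equal(named$name, c("Ofu-m0001_5p", "Ofu-m0002_3p"))
  # exact duplicates collapse; empty input stays empty
  named <- name_candidates(acc[c(1, 1), ])
  expect_equal(nrow(named), 1L)
  expect_equal(nrow(name_candidates(acc[0, ])), 0L)
})
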