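# Normalization, fold-change and the count-based significance test.
# The published table's strain totals are the sums of the two
# replicates' clean reads: resistant 5,804,468 + 5,834,651 and
# susceptible 5,763,509 + 5,840,702.

TOTAL_R <- 5804468 + 5834651
TOTAL_S <- 5763509 + 5840702

test_that("normalization reproduces published values to 4 decimals", {
  expect_equal(round(normalize_expression(31180, TOTAL_R), 4), 2678.8969)
  expect_equal(round(normalize_expression(18929, TOTAL_S), 4), 1631.2182)
  expect_equal(round(normalize_expression(7305, TOTAL_R), 4), 627.6248)
  expect_equal(round(normalize_expression(10244, TOTAL_R), 4), 880.1353)
  expect_equal(round(normalize_expression(2000, TOTAL_S), 4), 172.3512)
  # zero substitution and the identity scale
  expect_equal(normalize_expression(0, TOTAL_R), 0.01)
  expect_equal(normalize_expression(1e6, 1e6), 1e6)
  expect_error(normalize_expression(10, 0), "positive")
  expect_error(normalize_expression(-1, 10), "non-negative")
})

test_that("fold-changes reproduce published values to 4 decimals", {
  fc <- function(cr, cc, tr = TOTAL_R, ts = TOTAL_S)
    round(fold_change(normalize_expression(cr, tr),
                      normalize_expression(cc, ts)), 4)
  expect_equal(fc(31180, 0), 18.0313)
  expect_equal(fc(30, 0), 8.0098)
  expect_equal(fc(7305, 18929), -1.3780)
  expect_equal(fc(3840, 3168), 0.2732)
  expect_equal(fc(10244, 2000), 2.3524)
  expect_equal(fc(2, 454), -7.8309)
  expect_equal(fold_change(5, 5), 0)
  # antisymmetry
  set.seed(3)
  a <- runif(20, 0.01, 1e4); b <- runif(20, 0.01, 1e4)
  expect_equal(fold_change(a, b), -fold_change(b, a))
})

test_that("count_p_value matches the direct-summation oracle", {
  expect_equal(count_p_value(5, 5, 1e6, 1e6), 1)
  expect_equal(count_p_value(0, 8, 1e6, 1e6), ac_oracle(0, 8, 1e6, 1e6),
               tolerance = 1e-10)
  set.seed(31)
  for (i in 1:25) {
    x <- rpois(1, 50); y <- rpois(1, 50)
    N1 <- runif(1, 1e5, 1e7); N2 <- runif(1, 1e5, 1e7)
    p <- count_p_value(x, y, N1, N2)
    o <- ac_oracle(x, y, N1, N2)
    expect_equal(p, o, tolerance = 1e-10,
                 label = sprintf("x=%d y=%d", x, y))
    expect_gt(p, 0); expect_lte(p, 1)
  }
  expect_error(count_p_value(-1, 2, 10, 10), "non-negative")
  expect_error(count_p_value(1, 2, 0, 10), "positive")
})

test_that("count_p_value is symmetric up to discreteness, and monotone", {
  # the prescribed two-sided tail rule includes the observed point in
  # both tails, so swapping (x, N1) <-> (y, N2) can shift the p-value
  # by at most twice the observed point's probability mass
  set.seed(37)
  for (i in 1:10) {
    x <- rpois(1, 30); y <- rpois(1, 30)
    N <- runif(1, 1e5, 1e7)
    pm <- exp(mirflow:::.ac_log_term(y, x, 0, log(2)))
    expect_lte(abs(count_p_value(x, y, N, N) -
                     count_p_value(y, x, N, N)),
               2 * pm + 1e-12)
  }
  p <- vapply(1:50, function(y) count_p_value(0, y, 1e6, 1e6), 0)
  expect_true(all(diff(p) < 0))
})

test_that("replicate_pearson handles exact and degenerate cases", {
  x <- c(1, 5, 9, 2)
  expect_equal(replicate_pearson(x, x), 1)
  expect_equal(replicate_pearson(x, mean(x) - (x - mean(x))), -1)
  expect_error(replicate_pearson(x, x[1:3]), "equal length")
  expect_error(replicate_pearson(c(1, 1), c(2, 3)), "constant")
})

test_that("de_table pools replicates, filters and sorts", {
  counts <- rbind(
    "miR-a" = c(S1 = 0L, S2 = 0L, R1 = 15000L, R2 = 16180L),
    "miR-b" = c(S1 = 1000L, S2 = 1000L, R1 = 5122L, R2 = 5122L),
    "miR-c" = c(S1 = 2L, S2 = 2L, R1 = 2L, R2 = 2L))  # all norm < 1
  totals <- c(S1 = 5763509, S2 = 5840702, R1 = 5804468, R2 = 5834651)
  de <- de_table(counts, totals,
                 groups = list(control = c("S1", "S2"),
                               treated = c("R1", "R2")))
  expect_equal(nrow(de), 2L)  # the low-expression row is dropped
  a <- de[de$mirna == "miR-a", ]
  expect_equal(round(a$treated_norm, 4), 2678.8969)
  expect_equal(a$control_norm, 0.01)
  expect_equal(round(a$fold_change, 4), 18.0313)
  expect_true(a$significant)
  expect_equal(de$p_value, sort(de$p_value))
  # zero substitution is never applied to the raw counts entering p
  expect_equal(a$control_count, 0L)
})

test_that("significance is calibrated on null Poisson draws", {
  set.seed(41)
  n <- 300
  lambda <- runif(n, 5, 500)
  x <- rpois(n, lambda); y <- rpois(n, lambda)
  p <- vapply(seq_len(n), function(i)
    count_p_value(x[i], y[i], 1e6, 1e6), 0)
  expect_lte(mean(p < 0.05), 0.08)
})
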