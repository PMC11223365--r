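test_that("the published subtype table reproduces its printed row percents", {
  counts <- ccs_table1_counts()
  pct_O <- round_half_up(100 * counts["O", ] / sum(counts["O", ]), 2)
  pct_nonO <- round_half_up(100 * counts["non_O", ] / sum(counts["non_O", ]), 2)
  expect_equal(unname(pct_O), c(25.12, 6.85, 28.59, 0.74, 38.70))
  expect_equal(unname(pct_nonO), c(30.19, 7.07, 26.33, 0.82, 35.59))
  ht <- chi_square_test(counts)
  expect_equal(ht$df, 4L)
  expect_lt(ht$p_value, 1e-4)
})

test_that("build_contingency assembles counts, percents and the omnibus test", {
  bt <- rep(c("O", "non_O", "missing"), c(40, 60, 5))
  lab <- c(rep(c("LAA", "SAO"), c(10, 30)), rep(c("LAA", "SAO"), c(30, 30)),
           rep("LAA", 5))
  expect_message(tab <- build_contingency(bt, lab), "5 sample")
  expect_equal(sum(tab$counts), 100)
  expect_equal(unname(rowSums(tab$row_percents)), c(100, 100))
  expect_equal(tab$df, 1L)
  # identical row distributions give chi2 = 0, p = 1
  tab0 <- build_contingency(rep(c("O", "non_O"), each = 40),
                            rep(rep(c("LAA", "SAO"), each = 20), 2))
  expect_equal(tab0$chi2, 0)
  expect_equal(tab0$p_value, 1)
})

test_that("chi-square statistic equals the direct sum over expected counts", {
  counts <- ccs_table1_counts()
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  direct <- sum((counts - expected)^2 / expected)
  expect_equal(chi_square_test(counts)$chi2, direct)
  # degenerate and perfectly associated corners
  expect_equal(chi_square_test(matrix(10, 2, 2))$p_value, 1)
  expect_lt(chi_square_test(matrix(c(20, 0, 0, 20), 2))$p_value, 1e-8)
  expect_error(chi_square_test(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)),
               "marginal")
})

test_that("odds ratios follow ad/bc with Haldane-Anscombe fallback", {
  flat <- odds_ratio(matrix(10, 2, 2))
  expect_equal(flat$or, 1)
  expect_true(flat$ci_low < 1 && flat$ci_high > 1)

  t1 <- matrix(c(2030, 4693, 708, 2111), 2, 2, byrow = TRUE)
  expect_equal(odds_ratio(t1)$or, (2030 * 2111) / (4693 * 708))

  zed <- odds_ratio(matrix(c(5, 0, 5, 5), 2, 2, byrow = TRUE))
  expect_true(zed$corrected)
  expect_equal(zed$or, (5.5 * 5.5) / (0.5 * 5.5))
  expect_error(odds_ratio(matrix(c(-1, 2, 3, 4), 2)), "negative")
})

test_that("rank-sum p-values match literal enumeration for small groups", {
  # the classic separated case: one assignment per tail out of C(6,3) = 20
  res <- wilcoxon_rank_sum(1:3, 4:6)
  expect_equal(res$method, "exact")
  expect_equal(res$p_value, 2 / 20)

  set.seed(17)
  for (i in 1:20) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    x <- sample(1:6, n1, TRUE)   # heavy ties on purpose
    y <- sample(1:6, n2, TRUE)
    if (length(unique(c(x, y))) == 1) next
    expect_equal(wilcoxon_rank_sum(x, y)$p_value, ranksum_enumerate(x, y),
                 tolerance = 1e-12)
  }
})

test_that("rank-sum p is invariant to swapping group labels", {
  set.seed(23)
  x <- rnorm(7); y <- rnorm(5)
  expect_equal(wilcoxon_rank_sum(x, y)$p_value, wilcoxon_rank_sum(y, x)$p_value)
  xl <- rnorm(30); yl <- rnorm(45)
  expect_equal(wilcoxon_rank_sum(xl, yl)$p_value, wilcoxon_rank_sum(yl, xl)$p_value)
})

test_that("the large-sample branch agrees with the standard implementation", {
  set.seed(29)
  x <- rnorm(25); y <- rnorm(30, 0.3)
  ours <- wilcoxon_rank_sum(x, y)
  expect_equal(ours$method, "normal")
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  # and under ties
  xt <- sample(1:10, 25, TRUE); yt <- sample(1:10, 30, TRUE)
  expect_equal(wilcoxon_rank_sum(xt, yt)$p_value,
               stats::wilcox.test(xt, yt, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-10)
})

test_that("identical samples are a degenerate null", {
  expect_equal(wilcoxon_rank_sum(rep(2, 5), rep(2, 9))$p_value, 1)
})

test_that("study-population exclusion arithmetic checks its intermediates", {
  res <- cohort_filter(10241, 11, 688, 2174)
  expect_equal(res$n_is, 9542)
  expect_equal(res$n_first_ever, 7368)
  expect_equal(cohort_filter(100, 0, 0, 0), list(n_is = 100, n_first_ever = 100))
  expect_error(cohort_filter(10, 5, 6, 0), "exceed")
  expect_error(cohort_filter(10, -1, 0, 0), "non-negative")
})

test_that("chi-square power at the cohort scale matches the noncentral closed form", {
  # resampling the published joint distribution at n = 9,542 makes the Pearson
  # statistic noncentral chi-square with ncp equal to the table's own chi2
  counts <- ccs_table1_counts()
  chi2 <- chi_square_test(counts)$chi2
  expected_power <- pchisq(qchisq(1 - 1e-4, 4), 4, ncp = chi2,
                           lower.tail = FALSE)
  p_o <- sum(counts["O", ]) / sum(counts)
  n_seeds <- 50
  rej <- vapply(seq_len(n_seeds), function(seed) {
    cfg <- sim_config(n_samples = 9542, seed = 700 + seed)
    set.seed(700 + seed)
    bt <- ifelse(stats::runif(9542) < p_o, "O", "non_O")
    labs <- gen_cohort_labels(bt, cfg)
    chi_square_test(unclass(table(labs$blood_type, labs$subtype)))$p_value
  }, numeric(1))
  se <- sqrt(expected_power * (1 - expected_power) / n_seeds)
  expect_lt(abs(mean(rej < 1e-4) - expected_power), 3 * se)
  # at the conventional alpha the association is detected essentially always
  expect_gte(mean(rej < 0.05), 0.95)
})

test_that("group_comparison dispatches by variable type", {
  set.seed(5)
  bt <- rep(c("O", "non_O"), c(30, 40))
  x <- c(rnorm(30, 1), rnorm(40, 3))
  gc <- group_comparison(x, bt, "continuous")
  expect_equal(gc$test, "wilcoxon")
  expect_lt(gc$p_value, 0.01)
  expect_named(gc$summaries$O, c("median", "q1", "q3"))
  gcc <- group_comparison(sample(c("yes", "no"), 70, TRUE), bt, "categorical")
  expect_equal(gcc$test, "chi_square")
  expect_true(gcc$p_value >= 0 && gcc$p_value <= 1)
})
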