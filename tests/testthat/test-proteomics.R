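test_that("null data yields the nominal false-positive fraction", {
  set.seed(41)
  m <- matrix(2^rnorm(2000 * 20, 20, 1), nrow = 2000)
  group <- rep(c("O", "non_O"), each = 10)
  de <- differential_expression(m, group)
  frac <- mean(de$p_value < 0.05, na.rm = TRUE)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
  # the combined volcano threshold is far more selective than alpha alone
  expect_lt(mean(de$volcano_class != "not_significant"), 0.02)
})

test_that("volcano classification follows the p and fold-change thresholds", {
  set.seed(43)
  base <- matrix(2^rnorm(3 * 12, 18, 0.1), nrow = 3)
  group <- rep(c("O", "non_O"), each = 6)
  m <- base
  m[1, group == "O"] <- m[1, group == "O"] * 2^3   # strong up: log2fc ~ 3
  m[2, group == "O"] <- m[2, group == "O"] * 2^0.5 # significant but below fc cut
  de <- differential_expression(m, group)
  expect_equal(de$volcano_class, c("up", "not_significant", "not_significant"))
  # linear fold-change scale moves the cut to log2(1.2)
  de_lin <- differential_expression(m, group, fc_scale = "linear")
  expect_equal(de_lin$volcano_class[2], "up")
})

test_that("constant proteins are flagged, not tested", {
  m <- rbind(rep(8, 8), 2^rnorm(8, 3, 1))
  group <- rep(c("O", "non_O"), each = 4)
  de <- differential_expression(m, group)
  expect_true(de$flagged[1])
  expect_equal(de$volcano_class[1], "not_significant")
})

test_that("results are invariant to column order and global scaling", {
  set.seed(47)
  cfg <- sim_config(seed = 47, n_proteins = 60, n_up = 5, n_down = 5,
                    n_per_group = 8)
  pr <- gen_proteome(cfg)
  de <- differential_expression(pr$intensities, pr$group)
  perm <- sample(ncol(pr$intensities))
  de_perm <- differential_expression(pr$intensities[, perm], pr$group[perm])
  expect_equal(de_perm$log2fc, de$log2fc, tolerance = 1e-12)
  expect_equal(de_perm$p_value, de$p_value, tolerance = 1e-12)
  de_scaled <- differential_expression(pr$intensities * 1000, pr$group)
  expect_equal(de_scaled$log2fc, de$log2fc, tolerance = 1e-9)
})

test_that("planted differential proteins are recovered in the right class", {
  hits <- vapply(1:3, function(seed) {
    pr <- gen_proteome(sim_config(seed = seed))
    de <- differential_expression(pr$intensities, pr$group)
    mean(de$volcano_class[pr$truth$direction != "none"] ==
           pr$truth$direction[pr$truth$direction != "none"])
  }, numeric(1))
  expect_true(all(hits >= 0.9))
})

test_that("hypergeometric enrichment matches closed forms and enumeration", {
  bg <- sprintf("P%02d", 1:20)
  terms <- list(t5 = bg[1:5], small = bg[1:2])
  res <- overrepresentation(bg[1:5], bg, terms)
  expect_equal(res$p_value[res$term_id == "t5"], 1 / choose(20, 5))
  expect_false("small" %in% res$term_id)   # below min_term_size

  # query = background makes every term's enrichment certain: p = 1
  res_all <- overrepresentation(bg, bg, list(a = bg[1:6], b = bg[3:12]))
  expect_true(all(res_all$p_value == 1))

  # enumeration oracle on a background of 15
  bg15 <- sprintf("G%02d", 1:15)
  term <- bg15[1:6]
  query <- bg15[c(1:4, 10:12)]   # overlap 4, |query| = 7
  res15 <- overrepresentation(query, bg15, list(term = term))
  draws <- combn(15, 7)
  overlap_counts <- apply(draws, 2, function(idx) sum(bg15[idx] %in% term))
  expect_equal(res15$p_value, mean(overlap_counts >= 4))
})

test_that("BH q-values equal the brute-force step-up procedure", {
  set.seed(53)
  for (i in 1:10) {
    p <- runif(sample(3:50, 1))^sample(1:3, 1)
    expect_equal(stats::p.adjust(p, "BH"), bh_stepup(p), tolerance = 1e-14)
  }
  # and through the enrichment interface
  bg <- sprintf("X%03d", 1:100)
  set.seed(54)
  terms <- lapply(1:8, function(i) sample(bg, 20))
  names(terms) <- paste0("t", 1:8)
  res <- overrepresentation(sample(bg, 15), bg, terms)
  expect_equal(res$q_value, bh_stepup(res$p_value), tolerance = 1e-14)
})

test_that("a planted enriched term dominates the ranking", {
  first <- vapply(1:10, function(seed) {
    pr <- gen_proteome(sim_config(seed = seed))
    de <- differential_expression(pr$intensities, pr$group)
    query <- de$protein_id[de$volcano_class != "not_significant"]
    res <- overrepresentation(query, pr$truth$protein_id, pr$terms)
    res$term_id[1] == "planted_lipid_term"
  }, logical(1))
  expect_gte(mean(first), 0.9)
})

test_that("degenerate inputs are rejected", {
  expect_error(overrepresentation(character(0), "a", list(t = "a")), "non-empty")
  expect_error(overrepresentation("b", "a", list(t = "a")), "subset")
  m <- matrix(1:4, 2)
  expect_error(differential_expression(m, c("O", "non_O")), ">= 2 samples")
})

test_that("GMT files round-trip", {
  path <- withr::local_tempfile(fileext = ".gmt")
  terms <- list(alpha = c("P1", "P2", "P3"), beta = c("P2", "P9"))
  write_gmt(terms, path)
  expect_equal(read_gmt(path), terms)
})
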