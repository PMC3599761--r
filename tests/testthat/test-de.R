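test_that("normalize_cpm reproduces hand arithmetic and rejects bad totals", {
  expect_equal(normalize_cpm(150, 15220000), 150 / 15220000 * 1e6)
  expect_equal(normalize_cpm(150, 15220000), 9.855453, tolerance = 1e-6)
  expect_equal(normalize_cpm(c(0, 10), 1e6), c(0, 10))
  expect_error(normalize_cpm(5, 0), "positive")
})

test_that("fisher_test handles degenerate tables and is symmetric", {
  expect_equal(fisher_test(0, 0, 1000, 1000), 1)
  expect_equal(fisher_test(1000, 2000, 1000, 2000), 1)
  expect_equal(fisher_test(7, 3, 500, 400), fisher_test(3, 7, 400, 500))
  expect_error(fisher_test(-1, 0, 10, 10), "non-negative")
  expect_error(fisher_test(11, 0, 10, 10), "exceed")
})

test_that("fisher_test agrees with stats::fisher.test", {
  set.seed(31)
  for (i in 1:50) {
    NA_ <- sample(20:2000, 1); NB_ <- sample(20:2000, 1)
    a <- sample(0:min(NA_, 50), 1); b <- sample(0:min(NB_, 50), 1)
    tab <- matrix(c(a, NA_ - a, b, NB_ - b), nrow = 2)
    expect_equal(fisher_test(a, b, NA_, NB_),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9,
                 info = sprintf("a=%d b=%d NA=%d NB=%d", a, b, NA_, NB_))
  }
})

test_that("fisher_test agrees with the enumeration reference", {
  set.seed(32)
  for (i in 1:50) {
    NA_ <- sample(10:5000, 1); NB_ <- sample(10:5000, 1)
    a <- sample(0:min(NA_, 100), 1); b <- sample(0:min(NB_, 100), 1)
    expect_equal(fisher_test(a, b, NA_, NB_),
                 fisher_exact_reference(a, b, NA_, NB_), tolerance = 1e-12)
  }
})

test_that("expression_records computes CPM, fold change, and p-values", {
  rec <- expression_records(c("m1", "m2", "m3"),
                            count_A = c(100, 0, 50),
                            count_B = c(300, 20, 0),
                            N_A = 1e5, N_B = 2e5)
  expect_equal(rec$cpm_A, c(1000, 0, 500))
  expect_equal(rec$cpm_B, c(1500, 100, 0))
  expect_equal(rec$fold_change[1], 1.5)
  expect_equal(rec$log2_fold_change[1], log2(1.5))
  expect_true(is.na(rec$fold_change[2]) && is.na(rec$fold_change[3]))
  expect_equal(rec$p_value, fisher_test(rec$count_A, rec$count_B, 1e5, 2e5))
  # pseudocount only touches zero-count rows
  rec2 <- expression_records("m2", 0, 20, 1e5, 2e5, pseudocount = 1)
  expect_equal(rec2$fold_change, (20 / 2e5 + 1 / 2e5) / (1 / 1e5))
})

test_that("specificity classes follow the presence threshold", {
  rec <- data.frame(id = c("a", "b", "c", "d"),
                    count_A = c(5, 0, 3, 0), count_B = c(0, 7, 2, 0))
  cl <- classify_specificity(rec)
  expect_equal(cl$specificity,
               c("A_specific", "B_specific", "co_expressed", "co_expressed"))
  cl5 <- classify_specificity(rec, presence_threshold = 5)
  expect_equal(cl5$specificity[3], "co_expressed")  # both below threshold
  expect_equal(cl5$specificity[1], "A_specific")
})

test_that("call_de uses a strict p threshold on co-expressed records only", {
  rec <- expression_records(c("de", "null", "b_only"),
                            count_A = c(400, 100, 0),
                            count_B = c(100, 100, 500),
                            N_A = 1e6, N_B = 1e6)
  out <- call_de(rec, p_threshold = 0.001, fc_threshold = 1.5)
  expect_true(out$is_DE[out$id == "de"])
  expect_equal(out$direction[out$id == "de"], "down")
  expect_false(out$is_DE[out$id == "null"])
  # specific miRNAs are never DE however extreme the counts
  expect_false(out$is_DE[out$id == "b_only"])
  # exactly at the threshold is not DE (strict inequality)
  rec$specificity <- "co_expressed"
  rec$p_value <- c(0.001, 0.001 - 1e-9, 0.5)
  out2 <- call_de(rec)
  expect_equal(out2$is_DE, c(FALSE, TRUE, FALSE))
  # BH adjustment thresholds on adjusted p-values
  out3 <- call_de(rec, adjust = TRUE)
  expect_true("p_adjusted" %in% names(out3))
  expect_equal(out3$p_adjusted, stats::p.adjust(rec$p_value, "BH"))
})

test_that("call_de direction is 'up' for in-band DE with fold > 1", {
  rec <- data.frame(id = "x", count_A = 100, count_B = 120,
                    fold_change = 1.2, log2_fold_change = log2(1.2),
                    p_value = 1e-5, specificity = "co_expressed")
  out <- call_de(rec)
  expect_true(out$is_DE)
  expect_equal(out$direction, "up")
})

test_that("coexpression_summary percentages are rounded to 2 decimals", {
  rec <- data.frame(id = letters[1:3], count_A = c(1, 1, 0),
                    count_B = c(1, 0, 1))
  co <- coexpression_summary(classify_specificity(rec))
  expect_equal(co$n_total, 3L)
  expect_equal(co$n_coexpressed, 1L)
  expect_equal(co$percent, 33.33)
  expect_error(coexpression_summary(rec[0, ]), "no records")
})

test_that("abundance_summary reports top-n shares per library", {
  rec <- data.frame(id = c("m1", "m2", "m3", "m4"),
                    count_A = c(70, 20, 9, 1), count_B = c(10, 10, 40, 40))
  ab <- abundance_summary(rec, n = 2)
  expect_equal(unname(ab$share[["A"]]), 0.9)
  expect_equal(unname(ab$share[["B"]]), 0.8)
  expect_equal(ab$ranked$id[ab$ranked$library == "A"], c("m1", "m2"))
  # ties rank by id
  expect_equal(ab$ranked$id[ab$ranked$library == "B"], c("m3", "m4"))
  expect_warning(abundance_summary(rec, n = 10), "fewer records")
})
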