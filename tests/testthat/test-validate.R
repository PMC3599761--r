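test_that("probe collapse takes the per-sample median over probes", {
  m <- matrix(c(2, 4, 10,   1, 5, 9),
              nrow = 3, dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
  map <- c(p1 = "mir1", p2 = "mir1", p3 = "mir1")
  out <- collapse_probes_median(m, map)
  expect_equal(out$matrix["mir1", ], c(s1 = 4, s2 = 5))
  expect_equal(out$n_unmapped, 0L)
  # even number of probes: mean of the middle two
  m2 <- m[1:2, , drop = FALSE]
  out2 <- collapse_probes_median(m2, map)
  expect_equal(out2$matrix["mir1", "s1"], 3)
  # unmapped probes are dropped and counted
  out3 <- collapse_probes_median(m, c(p1 = "mir1", p2 = "mir1"))
  expect_equal(out3$n_unmapped, 1L)
  expect_equal(out3$matrix["mir1", "s1"], 3)
  expect_error(collapse_probes_median(m, character(0)), "empty")
})

test_that("quantile normalization matches the hand-worked example", {
  m <- cbind(a = c(1, 3), b = c(2, 6))
  qn <- quantile_normalize(m)
  # rank 1 values (1, 2) -> mean 1.5; rank 2 values (3, 6) -> mean 4.5
  expect_equal(unname(qn[, "a"]), c(1.5, 4.5))
  expect_equal(unname(qn[, "b"]), c(1.5, 4.5))
  # idempotent: already-normalized data is unchanged
  expect_equal(quantile_normalize(qn), qn)
  # columns share the same sorted values afterwards
  set.seed(61)
  big <- matrix(rnorm(60), ncol = 3)
  qb <- quantile_normalize(big)
  expect_equal(sort(qb[, 1]), sort(qb[, 2]))
  expect_equal(sort(qb[, 2]), sort(qb[, 3]))
  expect_error(quantile_normalize(m[, 1, drop = FALSE]), "2 columns")
  expect_error(quantile_normalize(cbind(c(1, NA), c(2, 3))), "non-finite")
})

test_that("upper-quartile scaling equalizes the 75th percentiles", {
  set.seed(62)
  m <- cbind(a = rexp(50, 1), b = rexp(50, 0.2))
  sc <- upper_quartile_scale(m)
  uq <- apply(sc, 2, quantile, probs = 0.75)
  expect_equal(unname(uq[1]), unname(uq[2]))
})

test_that("pearson matches cor.test", {
  set.seed(63)
  x <- rnorm(20); y <- x + rnorm(20, 0, 0.5)
  ct <- cor.test(x, y)
  p <- pearson(x, y)
  expect_equal(p$r, unname(ct$estimate))
  expect_equal(p$p, ct$p.value)
  expect_equal(p$n, 20L)
  expect_error(pearson(x, y[1:5]), "equal length")
  expect_error(pearson(1:2, 2:3), "at least 3")
  expect_error(pearson(rep(1, 5), 1:5), "zero variance")
})

test_that("replicate_correlation averages off-diagonal correlations", {
  set.seed(64)
  base <- rnorm(30)
  m <- cbind(r1 = base + rnorm(30, 0, 0.1), r2 = base + rnorm(30, 0, 0.1),
             r3 = base + rnorm(30, 0, 0.1))
  rr <- replicate_correlation(m)
  expect_equal(dim(rr$r), c(3L, 3L))
  expect_equal(rr$mean_r, mean(rr$r[upper.tri(rr$r)]))
  expect_gt(rr$mean_r, 0.9)
})

test_that("cross-platform concordance uses the identifier intersection", {
  seq_fc <- c(m1 = 1, m2 = -2, m3 = 0.5, m4 = 3)
  arr_fc <- c(m2 = -1.8, m3 = 0.4, m4 = 2.5, m9 = 7)
  cc <- cross_platform_concordance(seq_fc, arr_fc)
  expect_equal(cc$n, 3L)
  expect_equal(cc$r, unname(cor(seq_fc[c("m2", "m3", "m4")],
                                arr_fc[c("m2", "m3", "m4")])))
  expect_error(cross_platform_concordance(seq_fc[1:2], arr_fc),
               "fewer than 3")
})

test_that("simulated probe matrices are deterministic and well-formed", {
  expr <- matrix(c(8, 10, 12, 6, 10, 14), nrow = 3,
                 dimnames = list(c("m1", "m2", "m3"), c("muscle", "liver")))
  s1 <- simulate_probe_matrix(expr, seed = 5L)
  s2 <- simulate_probe_matrix(expr, seed = 5L)
  expect_identical(s1, s2)
  expect_false(identical(s1$probe_matrix,
                         simulate_probe_matrix(expr, seed = 6L)$probe_matrix))
  expect_equal(dim(s1$probe_matrix), c(9L, 6L))
  expect_equal(unname(s1$probe_to_mirna[["m2_p3"]]), "m2")
  # the simulated intensities recover the underlying expression ordering
  coll <- collapse_probes_median(s1$probe_matrix, s1$probe_to_mirna)
  muscle <- rowMeans(coll$matrix[, grep("^muscle", colnames(coll$matrix))])
  expect_equal(order(muscle), order(expr[, "muscle"]))
})

test_that("sequencing and simulated array fold changes are concordant", {
  # high-level validation loop: true log2 fold changes -> probe matrix ->
  # collapse + quantile normalize -> per-platform fold changes correlate
  set.seed(65)
  n <- 30
  lfc <- rnorm(n, 0, 2)
  base <- runif(n, 6, 12)
  expr <- cbind(A = base, B = base + lfc)
  rownames(expr) <- sprintf("mir%02d", seq_len(n))
  sim <- simulate_probe_matrix(expr, seed = 66L)
  coll <- collapse_probes_median(sim$probe_matrix, sim$probe_to_mirna)
  qn <- quantile_normalize(coll$matrix)
  raw_fc <- rowMeans(coll$matrix[, grep("^B", colnames(coll$matrix))]) -
    rowMeans(coll$matrix[, grep("^A", colnames(coll$matrix))])
  cc_raw <- cross_platform_concordance(setNames(lfc, rownames(expr)),
                                       raw_fc)
  expect_gt(cc_raw$r, 0.95)
  # quantile normalization equalizes the two tissues' distributions, which
  # compresses genuine cross-tissue differences: concordance drops but the
  # ranking survives
  arr_fc <- rowMeans(qn[, grep("^B", colnames(qn))]) -
    rowMeans(qn[, grep("^A", colnames(qn))])
  cc <- cross_platform_concordance(setNames(lfc, rownames(expr)), arr_fc)
  expect_gt(cc$r, 0.75)
  expect_equal(cc$n, n)
})
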