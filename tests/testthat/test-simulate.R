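small_cfg <- function(seed = 1L) {
  sim_config(seed = seed, genome_length = 12000L,
             n_known = 4L, n_conserved = 2L, n_candidate = 2L,
             n_contaminants = 3L,
             library_depths = c(A = 5000, B = 5000))
}

test_that("generate_genome and simulate_libraries are seed-deterministic", {
  cfg <- small_cfg(7L)
  d1 <- generate_genome(cfg)
  d2 <- generate_genome(small_cfg(7L))
  expect_identical(d1$genome, d2$genome)
  expect_identical(d1$truth, d2$truth)
  s1 <- simulate_libraries(d1)
  s2 <- simulate_libraries(d2)
  expect_identical(s1$reads, s2$reads)
  # a different seed changes the genome
  expect_false(identical(d1$genome, generate_genome(small_cfg(8L))$genome))
})

test_that("planted precursors fold into valid hairpins on the mature span", {
  ds <- generate_genome(small_cfg(3L))
  for (i in seq_len(nrow(ds$truth))) {
    row <- ds$truth[i, ]
    feats <- hairpin_features(fold(row$precursor),
                              c(row$mature_start, row$mature_end))
    expect_true(is_valid_hairpin(feats)$valid, info = row$name)
  }
})

test_that("plant_hairpin geometry gives 2 nt 3' overhangs and a near-revcomp star", {
  set.seed(41)
  for (i in 1:10) {
    k <- sample(20:24, 1); l <- sample(4:15, 1)
    h <- mirforge:::plant_hairpin(k, l, 18L)
    expect_equal(nchar(h$precursor), 2L + k + l + k + 4L)
    expect_equal(h$mature[2] - h$mature[1], k)
    expect_equal(h$star[2] - h$star[1], k)
    # planted arms (before the +2 overhang shift) are near reverse
    # complements: at most 2 designed mismatches
    if (h$arm == "5p") {
      mat <- substr(h$precursor, 3, 2 + k)
      star <- substr(h$precursor, 3 + k + l, 2 + k + l + k)
    } else {
      star <- substr(h$precursor, 3, 2 + k)
      mat <- substr(h$precursor, 3 + k + l, 2 + k + l + k)
    }
    mm <- sum(strsplit(mat, "")[[1]] != strsplit(rc(star), "")[[1]])
    expect_lte(mm, 2L)
    # the claimed spans are the planted arms shifted +2 (3' overhangs)
    expect_equal(sort(c(h$mature[1], h$star[1]))[1], 2L)
    expect_true(is_valid_hairpin(hairpin_features(fold(h$precursor),
                                                  h$mature))$valid)
  }
})

test_that("genome embeds each precursor at its truth locus", {
  ds <- generate_genome(small_cfg(5L))
  g <- ds$genome[["chr1"]]
  for (i in seq_len(nrow(ds$truth))) {
    row <- ds$truth[i, ]
    embedded <- substr(g, row$start + 1L, row$end)
    if (row$strand == "-") embedded <- rc(embedded)
    expect_equal(embedded, row$precursor, info = row$name)
    expect_equal(row$mature_seq,
                 substr(row$precursor, row$mature_start + 1L, row$mature_end))
  }
  # contaminants are planted on the plus strand
  for (j in seq_len(nrow(ds$other_rna))) {
    o <- ds$other_rna[j, ]
    expect_equal(substr(g, o$start + 1L, o$end), o$sequence)
  }
})

test_that("library depths and planted proportions are respected", {
  cfg <- small_cfg(9L)
  ds <- generate_genome(cfg)
  sim <- simulate_libraries(ds)
  expect_equal(names(sim$reads), c("A", "B"))
  expect_equal(unname(lengths(sim$reads)), c(5000L, 5000L))
  # default truth: fold change 1 everywhere, proportions equal
  expect_equal(ds$truth$prop_B, ds$truth$prop_A)
  expect_equal(ds$truth$fold_change, rep(1, nrow(ds$truth)))
  # miRNA share excludes contaminant and oversize fractions
  share <- 1 - cfg$contaminant_fraction - cfg$oversize_fraction
  expect_equal(sum(ds$truth$prop_A), share)
})

test_that("explicit fold changes propagate into condition-B proportions", {
  cfg <- sim_config(seed = 2L, genome_length = 12000L, n_known = 5L,
                    n_conserved = 0L, n_candidate = 0L, n_contaminants = 2L,
                    contaminant_fraction = 0.5,
                    mirna_weights = rep(1, 5),
                    true_fold_changes = c(4, 1, 1, 1, 1))
  ds <- generate_genome(cfg)
  expect_equal(ds$truth$prop_B[1] / ds$truth$prop_A[1], 4)
  expect_equal(ds$truth$prop_B[-1], ds$truth$prop_A[-1])
})

test_that("sim_config round-trips through YAML", {
  cfg <- small_cfg(13L)
  path <- tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_s3_class(back, "mf_sim_config")
  expect_equal(back$seed, cfg$seed)
  expect_equal(back$library_depths, cfg$library_depths)
  expect_equal(back$isomir_profile, cfg$isomir_profile)
  # the restored config drives an identical simulation
  expect_identical(generate_genome(back)$genome,
                   generate_genome(cfg)$genome)
})

test_that("the default isomiR profile is a proper distribution", {
  pr <- default_isomir_profile()
  expect_equal(sum(pr$prob), 1)
  expect_true(all(abs(pr$d5) <= 3 & abs(pr$d3) <= 3 & pr$subst <= 1))
  expect_true(any(pr$d5 == 0 & pr$d3 == 0 & pr$subst == 0))
})
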