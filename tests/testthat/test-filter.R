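adapter <- "TGGAATTCTCGGGTGCCAAGG"

test_that("trim_adapter removes the adapter at its leftmost occurrence", {
  insert <- "ACGTACGTACGTACGTACGTAC"
  r1 <- paste0(insert, adapter)                       # full adapter
  r2 <- paste0(insert, substr(adapter, 1, 9))         # partial >= min_overlap
  r3 <- paste0(insert, substr(adapter, 1, 5))         # too short an overlap
  r4 <- insert                                        # no adapter at all
  r5 <- paste0("AC", adapter, "GG", adapter)          # two occurrences
  tr <- trim_adapter(c(r1, r2, r3, r4, r5), adapter, min_overlap = 8)
  expect_equal(tr$trimmed[1], insert)
  expect_equal(tr$trimmed[2], insert)
  expect_equal(tr$trimmed[3], r3)
  expect_equal(tr$trimmed[4], r4)
  expect_equal(tr$trimmed[5], "AC")                   # leftmost occurrence
  expect_equal(tr$no_adapter, c(FALSE, FALSE, TRUE, TRUE, FALSE))
})

test_that("trim_adapter clamps min_overlap to the adapter length", {
  tr <- trim_adapter("ACGTACGTGGG", "GGG", min_overlap = 8)
  expect_equal(tr$trimmed, "ACGTACGT")
  expect_false(tr$no_adapter)
})

test_that("collapse_reads matches a table() oracle and sort contract", {
  set.seed(11)
  reads <- sample(c("ACGTACGTAC", "TTTTGGGGCC", "ACGTACGTAC", "GATTACA"),
                  200, replace = TRUE)
  tt <- collapse_reads(reads, "A")
  oracle <- table(reads)
  expect_equal(sum(tt$count_A), length(reads))
  expect_setequal(tt$sequence, names(oracle))
  expect_equal(tt$count_A[match(names(oracle), tt$sequence)],
               as.integer(oracle))
  expect_equal(tt$length, nchar(tt$sequence))
  expect_true(all(diff(tt$count_A) <= 0))
  empty <- collapse_reads(character(0), "B")
  expect_equal(nrow(empty), 0L)
  expect_true("count_B" %in% names(empty))
})

test_that("merge_tag_tables unions sequences with zero for absent tags", {
  a <- collapse_reads(c("AAACCCGGG", "AAACCCGGG", "TTTAAACCC"), "A")
  b <- collapse_reads(c("TTTAAACCC", "GGGTTTAAA"), "B")
  m <- merge_tag_tables(list(A = a, B = b))
  expect_setequal(m$sequence, c("AAACCCGGG", "TTTAAACCC", "GGGTTTAAA"))
  expect_equal(m$count_A[m$sequence == "GGGTTTAAA"], 0L)
  expect_equal(m$count_B[m$sequence == "AAACCCGGG"], 0L)
  expect_equal(sum(m$count_A), 3L)
  expect_equal(sum(m$count_B), 2L)
  tot <- m$count_A + m$count_B
  expect_true(all(diff(tot) <= 0))
})

test_that("size_filter bounds are inclusive", {
  tags <- data.frame(
    sequence = c(strrep("A", 9), strrep("C", 10), strrep("G", 25),
                 strrep("T", 40), strrep("A", 41)),
    length = c(9L, 10L, 25L, 40L, 41L),
    count_A = c(1L, 1L, 1L, 1L, 1L), stringsAsFactors = FALSE)
  sf <- size_filter(tags, 10, 40)
  expect_equal(sf$kept$length, c(10L, 25L, 40L))
  expect_equal(sf$removed$length, c(9L, 41L))
})

test_that("quality filters apply N, low-complexity, then min-count on totals", {
  tags <- data.frame(
    sequence = c("ACGTNACGTA",                        # N
                 "AAAAAAAAAC",                        # 9/10 A -> low complexity
                 "ACGTACGTAC",                        # kept
                 "TGCATGCATG"),                       # total 1+1 = 2 -> kept
    length = rep(10L, 4),
    count_A = c(5L, 4L, 3L, 1L),
    count_B = c(0L, 2L, 3L, 1L), stringsAsFactors = FALSE)
  qf <- quality_filters(tags, min_count = 2, homopolymer_fraction = 0.9)
  expect_setequal(qf$tags$sequence, c("ACGTACGTAC", "TGCATGCATG"))
  expect_equal(qf$removed_per_step$n_filter[["A"]], 5)
  expect_equal(qf$removed_per_step$low_complexity[["B"]], 2)
  # min_count is on the total across libraries: 1+1 = 2 survives
  expect_equal(unname(qf$removed_per_step$min_count), c(0, 0))
  # a singleton in one library only is removed at min_count = 3
  qf3 <- quality_filters(tags, min_count = 3, homopolymer_fraction = 0.9)
  expect_false("TGCATGCATG" %in% qf3$tags$sequence)
})

test_that("filter_cascade conserves reads through every step", {
  set.seed(21)
  good <- replicate(30, rand_dna(22))
  reads <- list(
    A = c(sample(good, 300, replace = TRUE), replicate(5, rand_dna(8)),
          rep(strrep("A", 20), 3), rep("ACGTNACGTAACGTNACGTA", 2)),
    B = c(sample(good, 250, replace = TRUE), replicate(4, rand_dna(45))))
  fc <- filter_cascade(reads, min_count = 2)
  rep_df <- fc$report
  # conservation within each row and chaining between consecutive filters
  expect_equal(rep_df$reads_out, rep_df$reads_in - rep_df$reads_removed)
  for (lib in c("A", "B")) {
    sub <- rep_df[rep_df$library == lib, ]
    expect_equal(sub$reads_in[1], length(reads[[lib]]))
    expect_equal(sub$reads_in[-1], sub$reads_out[-nrow(sub)])
    expect_equal(unname(fc$mappable_totals[[lib]]),
                 sub$reads_out[nrow(sub)])
  }
  expect_equal(names(fc$mappable_totals), c("A", "B"))
  # the surviving tags account exactly for the mappable totals
  expect_equal(sum(fc$tags$count_A), unname(fc$mappable_totals[["A"]]))
  expect_equal(sum(fc$tags$count_B), unname(fc$mappable_totals[["B"]]))
  expect_equal(unique(rep_df$filter),
               c("size_filter", "n_filter", "low_complexity", "min_count"))
})

test_that("length_histogram is count-weighted with fractions summing to 1", {
  tags <- data.frame(sequence = c("AAGGTTCCAA", "CCGGAATTCCG", "TTGGCCAATT"),
                     length = c(10L, 11L, 10L),
                     count_A = c(6L, 3L, 1L), count_B = c(0L, 5L, 5L),
                     stringsAsFactors = FALSE)
  h <- length_histogram(tags)
  expect_equal(h$count[h$library == "A" & h$length == 10], 7)
  expect_equal(sum(h$fraction[h$library == "A"]), 1)
  expect_equal(sum(h$fraction[h$library == "B"]), 1)
  expect_equal(h$fraction[h$library == "B" & h$length == 11], 0.5)
})
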