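make_tags <- function(seqs, count_A, count_B = 0L) {
  data.frame(sequence = seqs, length = nchar(seqs),
             count_A = rep_len(as.integer(count_A), length(seqs)),
             count_B = rep_len(as.integer(count_B), length(seqs)),
             stringsAsFactors = FALSE)
}

test_that("map_tags agrees with a naive quadratic alignment oracle", {
  set.seed(51)
  targets <- c(t1 = rand_dna(180), t2 = rand_dna(140))
  exact <- c(substr(targets[["t1"]], 21, 42),
             substr(targets[["t1"]], 100, 121),
             substr(targets[["t2"]], 5, 26))
  mut <- exact[1]
  substr(mut, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                 substr(mut, 10, 10))[1]
  mut2 <- exact[2]
  substr(mut2, 3, 3) <- setdiff(c("A", "C", "G", "T"),
                                substr(mut2, 3, 3))[1]
  substr(mut2, 15, 15) <- setdiff(c("A", "C", "G", "T"),
                                  substr(mut2, 15, 15))[1]
  rc_tag <- rc(substr(targets[["t2"]], 60, 81))
  tags <- unique(c(exact, mut, mut2, rc_tag, replicate(3, rand_dna(22))))
  for (mm in 0:1) {
    for (bs in c(FALSE, TRUE)) {
      expect_equal(map_tags(tags, targets, max_mismatch = mm,
                            both_strands = bs),
                   naive_map(tags, targets, max_mismatch = mm,
                             both_strands = bs),
                   info = sprintf("mm=%d both=%s", mm, bs))
    }
  }
})

test_that("map_tags skips N-containing tags and handles empty input", {
  targets <- c(t1 = "ACGTACGTACGTACGTACGT")
  out <- map_tags(c("ACGTNACGTA"), targets, max_mismatch = 1)
  expect_equal(nrow(out), 0L)
  expect_equal(nrow(map_tags(character(0), targets)), 0L)
  expect_named(out, c("tag", "target", "start", "end", "strand",
                      "mismatches"))
})

test_that("remove_other_rna removes matching tags and reports class fractions", {
  set.seed(52)
  feature <- rand_dna(80)
  other <- data.frame(name = "rRNA-01", class = "rRNA",
                      sequence = feature, stringsAsFactors = FALSE)
  hit_tag <- substr(feature, 11, 32)
  clean_tag <- rand_dna(22)
  tags <- make_tags(c(hit_tag, clean_tag), count_A = c(30L, 10L),
                    count_B = c(20L, 40L))
  rr <- remove_other_rna(tags, other, max_mismatch = 0)
  expect_equal(rr$tags$sequence, clean_tag)
  expect_equal(rr$removed$sequence, hit_tag)
  expect_equal(rr$removed$class, "rRNA")
  pa <- rr$class_proportions
  expect_equal(pa$fraction[pa$library == "A"], 30 / 40)
  expect_equal(pa$fraction[pa$library == "B"], 20 / 60)
  expect_warning(remove_other_rna(tags, other[0, ]), "empty")
})

test_that("extract_flanks windows, clips, and strand-flips correctly", {
  set.seed(53)
  contig <- rand_dna(300)
  genome <- c(chr1 = contig)
  loc <- list(chrom = "chr1", start = 100L, end = 180L, strand = "+")
  w <- extract_flanks(genome, loc, flank = 60)
  expect_equal(w$window_start, 40L)
  expect_equal(w$window_end, 240L)
  expect_equal(w$sequence, substr(contig, 41, 240))
  expect_equal(w$mature_span, c(60L, 140L))
  expect_equal(substr(w$sequence, 61, 140), substr(contig, 101, 180))
  # clipping at the contig start
  w0 <- extract_flanks(genome, list(chrom = "chr1", start = 20L, end = 60L,
                                    strand = "+"), flank = 60)
  expect_equal(w0$window_start, 0L)
  expect_equal(w0$mature_span, c(20L, 60L))
  # minus strand: window is reverse-complemented, span on mature sense
  wm <- extract_flanks(genome, list(chrom = "chr1", start = 100L,
                                    end = 180L, strand = "-"), flank = 60)
  expect_equal(wm$sequence, rc(substr(contig, 41, 240)))
  expect_equal(substr(wm$sequence, wm$mature_span[1] + 1,
                      wm$mature_span[2]),
               rc(substr(contig, 101, 180)))
  expect_error(extract_flanks(genome, list(chrom = "chrX", start = 1,
                                           end = 10, strand = "+")),
               "unknown contig")
})

test_that("detect_star accepts the planted duplex geometry and rejects others", {
  mat <- "TGAGGTAGTAGGTTGTATAGTT"          # 22 nt
  k <- nchar(mat)
  precursor <- paste0("GA", mat, "CAATTAGC", rc(mat), "TCGA")
  mature_span <- c(2L, 2L + k)             # planted mature arm
  star_span <- c(2L + k + 8L + 2L, 2L + k + 8L + 2L + k)  # +2 shift: 2 nt 3' overhangs
  expect_true(detect_star(precursor, mature_span, star_span))
  # works identically from a folded structure
  expect_true(detect_star(fold(precursor), mature_span, star_span))
  # flush duplex (no overhang) at max_overhang = 0
  flush <- c(2L + k + 8L, 2L + k + 8L + k)
  expect_true(detect_star(precursor, mature_span, flush, max_overhang = 0L))
  # overlapping spans (same arm) are never a star
  expect_false(detect_star(precursor, mature_span, c(4L, 4L + k)))
  # a span in the loop violates the overhang geometry
  expect_false(detect_star(precursor, mature_span, c(24L, 32L)))
  # 5' overhangs (negative 3' overhang on the mature) are rejected
  expect_false(detect_star(precursor, mature_span,
                           c(star_span[1] - 8L, star_span[2] - 8L)))
})

test_that("tier precedence is known_species over conserved_mammal", {
  set.seed(54)
  h1 <- mirforge:::plant_hairpin(22L, 8L, 18L)
  h2 <- mirforge:::plant_hairpin(21L, 10L, 18L)
  known <- c("ssc-mir-1" = h1$precursor)
  mammal <- c("hsa-mir-1" = h1$precursor,   # same precursor, other species
              "hsa-mir-2" = h2$precursor)
  m1 <- substr(h1$precursor, h1$mature[1] + 1, h1$mature[2])
  m2 <- substr(h2$precursor, h2$mature[1] + 1, h2$mature[2])
  tags <- make_tags(c(m1, m2), count_A = c(50L, 40L), count_B = c(50L, 40L))
  anno <- classify_tiers(tags, known, mammal, genome = NULL)
  df <- anno$annotations
  expect_equal(df$tier[df$representative_tag == m1], "known_species")
  expect_equal(df$tier[df$representative_tag == m2], "conserved_mammal")
  # the shared precursor is annotated once, under the known-species tier
  expect_equal(sum(df$representative_tag == m1), 1L)
  tt <- anno$tier_table
  expect_equal(tt$n_mirna[tt$tier == "known_species"], 1L)
  expect_equal(tt$n_mirna[tt$tier == "conserved_mammal"], 1L)
  expect_equal(tt$n_mirna[tt$tier == "candidate"], 0L)
})

test_that("star tags are flagged within known precursors", {
  set.seed(55)
  h <- mirforge:::plant_hairpin(22L, 8L, 18L)
  known <- c("ssc-mir-9" = h$precursor)
  m <- substr(h$precursor, h$mature[1] + 1, h$mature[2])
  s <- substr(h$precursor, h$star[1] + 1, h$star[2])
  tags <- make_tags(c(m, s), count_A = c(100L, 5L), count_B = c(90L, 4L))
  anno <- classify_tiers(tags, known,
                         setNames(character(0), character(0)),
                         genome = NULL)
  df <- anno$annotations
  expect_equal(nrow(df), 2L)
  expect_false(df$is_star[df$representative_tag == m])
  star_row <- df[df$representative_tag == s, ]
  expect_true(star_row$is_star)
  expect_true(grepl("\\*$", star_row$name))
  expect_equal(star_row$mature_partner, df$name[df$representative_tag == m])
  tt <- anno$tier_table
  expect_equal(tt$n_star[tt$tier == "known_species"], 1L)
  expect_equal(tt$n_mirna[tt$tier == "known_species"], 1L)
})

test_that("candidate calling requires tags longer than 18 nt and a hairpin", {
  cfg <- sim_config(seed = 6L, genome_length = 8000L, n_known = 0L,
                    n_conserved = 0L, n_candidate = 2L, n_contaminants = 0L,
                    contaminant_fraction = 0, n_decoy_known = 0L,
                    n_decoy_mammal = 0L)
  ds <- generate_genome(cfg)
  empty_cat <- setNames(character(0), character(0))
  tags <- make_tags(ds$truth$mature_seq, count_A = 20L, count_B = 20L)
  anno <- classify_tiers(tags, empty_cat, empty_cat, ds$genome)
  df <- anno$annotations
  expect_equal(nrow(df), 2L)
  expect_true(all(df$tier == "candidate"))
  expect_true(all(!df$is_star))
  # 18 nt tags are excluded from candidate calling (> 18 nt rule)
  short <- make_tags(substr(ds$truth$mature_seq, 1, 18),
                     count_A = 20L, count_B = 20L)
  anno18 <- classify_tiers(short, empty_cat, empty_cat, ds$genome)
  expect_equal(nrow(anno18$annotations), 0L)
  # random tags with no hairpin context are not called
  set.seed(56)
  rand_tags <- make_tags(replicate(3, rand_dna(22)), 20L, 20L)
  anno_r <- classify_tiers(rand_tags, empty_cat, empty_cat, ds$genome)
  expect_equal(nrow(anno_r$annotations), 0L)
  # without a genome, candidate calling is skipped with a warning
  expect_warning(classify_tiers(tags, empty_cat, empty_cat, NULL),
                 "candidate calling skipped")
})
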