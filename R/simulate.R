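# Synthetic two-library small RNA-seq data with known ground truth.
# Pre-miRNA hairpins are planted by construction (mature arm + loop +
# mismatched reverse complement, with 2 nt terminal pads giving canonical
# 2 nt 3' duplex overhangs), so every planted precursor is a valid hairpin
# at any requested stem length. Contaminating other-RNA features carry
# class labels, making other-RNA removal exactly testable.

OTHER_RNA_CLASSES <- c("rRNA", "tRNA", "snRNA", "snoRNA", "mRNA", "repeat")

#' Default isomiR variant profile
#'
#' Distribution over (5' offset, 3' offset, substitution) isomiR variants
#' of a mature miRNA. Offsets are in nt on the mature sense strand
#' (positive `d5` trims the 5' end, positive `d3` extends the 3' end with
#' the templated genomic base). The unmodified mature sequence is the most
#' probable variant, so a family's most abundant member tracks its total
#' abundance, as observed in real libraries.
#'
#' @return Data.frame with columns `d5`, `d3`, `subst`, `prob` (probs sum
#'   to 1).
#' @export
default_isomir_profile <- function() {
  data.frame(
    d5    = c(0L,    0L,    0L,    0L,    1L,   -1L,    0L),
    d3    = c(0L,   -1L,    1L,   -2L,    0L,    0L,    0L),
    subst = c(0L,    0L,    0L,    0L,    0L,    0L,    1L),
    prob  = c(0.60,  0.14,  0.08,  0.05,  0.04,  0.03,  0.06))
}

#' Build and validate a simulation configuration
#'
#' Defines the study conditions emulated by the generator: two pooled
#' small RNA libraries from planted pre-miRNA hairpins across the three
#' annotation tiers, with skewed abundances, isomiR variation dominated by
#' the canonical mature sequence, low-abundance star reads, contaminating
#' other-RNA fragments, a small oversize tail to exercise size selection,
#' and per-base sequencing substitution error.
#'
#' @param seed Integer seed; a fixed seed yields byte-identical outputs.
#' @param genome_length Background genome length in bases.
#' @param n_known,n_conserved,n_candidate Planted precursors per tier
#'   (same-species catalog, other-mammal catalog, neither).
#' @param n_contaminants Number of planted other-RNA features.
#' @param mature_length_range Inclusive mature length bounds in nt, within
#'   10-40.
#' @param stem_pairs_min Minimum designed Watson-Crick pairs in each
#'   planted stem.
#' @param loop_length_range Inclusive hairpin loop length bounds in nt.
#' @param library_depths Named vector of reads per library (exactly two
#'   libraries).
#' @param contaminant_fraction Proportion of library-A reads drawn from
#'   other-RNA features.
#' @param oversize_fraction Proportion of reads longer than 40 nt (random
#'   genomic fragments), exercising the size filter.
#' @param error_rate Per-base substitution probability.
#' @param star_fraction Fraction of each miRNA's reads drawn from the star
#'   arm.
#' @param abundance_sdlog Log-normal sdlog for sampled miRNA abundances
#'   (skewed, as in real libraries).
#' @param mirna_weights Optional explicit relative abundances, one per
#'   planted precursor (overrides sampling).
#' @param true_fold_changes Optional per-precursor positive fold changes of
#'   library B relative to A on the normalized scale (default all 1).
#'   Condition-B proportions are `prop_A * fold`; the contaminant share
#'   absorbs the difference so that non-changing miRNAs keep a true
#'   normalized fold of exactly 1.
#' @param prop_A,prop_B Optional explicit per-precursor read proportions
#'   per condition (override weights and fold changes; entries may be 0 to
#'   plant library-specific miRNAs; each must sum to at most 1, the
#'   remainder going to contaminants).
#' @param isomir_profile Data.frame as [default_isomir_profile()].
#' @param n_decoy_known,n_decoy_mammal Catalog-only decoy precursors (not
#'   planted in the genome, never sequenced).
#'
#' @return A validated list of class `mf_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 30000L,
                       n_known = 20L, n_conserved = 15L, n_candidate = 15L,
                       n_contaminants = 10L,
                       mature_length_range = c(20L, 24L),
                       stem_pairs_min = 18L,
                       loop_length_range = c(4L, 15L),
                       library_depths = c(A = 100000, B = 100000),
                       contaminant_fraction = 0.20,
                       oversize_fraction = 0.01,
                       error_rate = 0.001,
                       star_fraction = 0.05,
                       abundance_sdlog = 1.5,
                       mirna_weights = NULL,
                       true_fold_changes = NULL,
                       prop_A = NULL, prop_B = NULL,
                       isomir_profile = default_isomir_profile(),
                       n_decoy_known = 5L, n_decoy_mammal = 20L) {
  cfg <- list(seed = as.integer(seed), genome_length = as.integer(genome_length),
              n_known = as.integer(n_known), n_conserved = as.integer(n_conserved),
              n_candidate = as.integer(n_candidate),
              n_contaminants = as.integer(n_contaminants),
              mature_length_range = as.integer(mature_length_range),
              stem_pairs_min = as.integer(stem_pairs_min),
              loop_length_range = as.integer(loop_length_range),
              library_depths = library_depths,
              contaminant_fraction = contaminant_fraction,
              oversize_fraction = oversize_fraction,
              error_rate = error_rate, star_fraction = star_fraction,
              abundance_sdlog = abundance_sdlog,
              mirna_weights = mirna_weights,
              true_fold_changes = true_fold_changes,
              prop_A = prop_A, prop_B = prop_B,
              isomir_profile = isomir_profile,
              n_decoy_known = as.integer(n_decoy_known),
              n_decoy_mammal = as.integer(n_decoy_mammal))
  n <- cfg$n_known + cfg$n_conserved + cfg$n_candidate
  fr <- c(cfg$contaminant_fraction, cfg$oversize_fraction, cfg$error_rate,
          cfg$star_fraction)
  if (any(fr < 0) || any(fr > 1)) stop("all fractions must lie in [0, 1]")
  if (length(cfg$library_depths) != 2L || is.null(names(cfg$library_depths)))
    stop("library_depths must be a named vector of two library depths")
  if (any(cfg$library_depths <= 0)) stop("library depths must be positive")
  if (cfg$mature_length_range[1L] < 10L || cfg$mature_length_range[2L] > 40L)
    stop("mature_length_range must lie within [10, 40]")
  if (cfg$mature_length_range[1L] < cfg$stem_pairs_min)
    stop("mature_length_range minimum must be >= stem_pairs_min")
  if (!is.null(cfg$true_fold_changes)) {
    if (length(cfg$true_fold_changes) != n || any(cfg$true_fold_changes <= 0))
      stop("true_fold_changes must give one positive value per precursor")
  }
  if (!is.null(cfg$mirna_weights) &&
      (length(cfg$mirna_weights) != n || any(cfg$mirna_weights <= 0)))
    stop("mirna_weights must give one positive weight per precursor")
  if (xor(is.null(cfg$prop_A), is.null(cfg$prop_B)))
    stop("prop_A and prop_B must be given together")
  if (!is.null(cfg$prop_A)) {
    if (length(cfg$prop_A) != n || length(cfg$prop_B) != n ||
        any(cfg$prop_A < 0) || any(cfg$prop_B < 0) ||
        sum(cfg$prop_A) > 1 + 1e-9 || sum(cfg$prop_B) > 1 + 1e-9)
      stop("prop_A/prop_B must be per-precursor proportions summing to <= 1")
  }
  if (abs(sum(cfg$isomir_profile$prob) - 1) > 1e-8)
    stop("isomir_profile probabilities must sum to 1")
  if (cfg$contaminant_fraction > 0 && cfg$n_contaminants == 0L)
    stop("contaminant_fraction > 0 requires n_contaminants > 0")
  class(cfg) <- "mf_sim_config"
  cfg
}

#' Save or load a simulation configuration as YAML
#'
#' @param config An `mf_sim_config`.
#' @param path YAML file path.
#' @return `path` invisibly (`write_sim_config`); the restored
#'   `mf_sim_config` (`read_sim_config`).
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "mf_sim_config"))
  x <- unclass(config)
  x$isomir_profile <- as.list(x$isomir_profile)
  x$library_depths <- as.list(x$library_depths)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$isomir_profile <- as.data.frame(x$isomir_profile)
  x$library_depths <- unlist(x$library_depths)
  do.call(sim_config, x)
}

# Plant one hairpin precursor: mature arm M, loop L, and a star arm that is
# the reverse complement of M with 0-2 internal mismatches, padded by 2 nt
# on both precursor ends so the mature/star duplex has 2 nt 3' overhangs.
#
# The construction is verified against the folding module: the planted
# duplex is almost always the realized maximum-weight structure, but for a
# small fraction of draws (about 1%) an unrelated pairing involving the
# loop or pads scores strictly higher and shreds the stem. The generator
# guarantees that every planted precursor passes is_valid_hairpin (at the
# default fold weights and thresholds), so such draws are redrawn; this is
# verification of a constructed hairpin, not rejection sampling of random
# sequence.
plant_hairpin <- function(k, loop_len, stem_pairs_min, max_tries = 100L) {
  for (try in seq_len(max_tries)) {
    arm <- sample(c("5p", "3p"), 1L)
    mat_arm <- random_dna(1L, k)
    n_mm <- sample.int(min(2L, k - stem_pairs_min) + 1L, 1L) - 1L
    star_arm <- revcomp(mat_arm)
    if (n_mm > 0L) {
      pos <- sample(4:(k - 4L), n_mm)   # keep duplex ends clean
      for (p in pos) {
        old <- substr(star_arm, p, p)
        substr(star_arm, p, p) <-
          sample(setdiff(c("A", "C", "G", "T"), old), 1L)
      }
    }
    # The mature/star spans below are shifted +2 relative to the planted
    # arms to create the canonical 2 nt 3' overhangs, which consumes two of
    # the pad3 bases; pad3 is 4 nt so that templated 3' isomiR extensions
    # of the flush arm stay inside the precursor.
    pad5 <- random_dna(1L, 2L); pad3 <- random_dna(1L, 4L)
    loop <- random_dna(1L, loop_len)
    if (arm == "5p") {
      precursor <- paste0(pad5, mat_arm, loop, star_arm, pad3)
      mature <- c(2L, 2L + k)
      star <- c(2L + k + loop_len + 2L, 2L + k + loop_len + 2L + k)
    } else {
      precursor <- paste0(pad5, star_arm, loop, mat_arm, pad3)
      mature <- c(2L + k + loop_len + 2L, 2L + k + loop_len + 2L + k)
      star <- c(2L, 2L + k)
    }
    ok <- is_valid_hairpin(hairpin_features(fold(precursor), mature))$valid
    if (ok)
      return(list(precursor = precursor, arm = arm, mature = mature,
                  star = star))
  }
  stop("could not construct a fold-valid hairpin in ", max_tries, " tries")
}

#' Generate a random genome with planted precursors and ground truth
#'
#' Plants `n_known + n_conserved + n_candidate` hairpin precursors and
#' `n_contaminants` other-RNA features at non-overlapping loci (random
#' strand for precursors) in a random background genome, and derives the
#' precursor catalogs: known-tier precursors appear in the same-species
#' catalog, conserved-tier precursors in the other-mammal catalog (under
#' other-species names), candidate-tier precursors in neither. Decoy
#' catalog entries are added to both catalogs.
#'
#' @param config An `mf_sim_config` from [sim_config()].
#'
#' @return A list of class `mf_sim_dataset` with elements `genome` (named
#'   character, one contig), `truth` (ground-truth data.frame: name, tier,
#'   locus in 0-based half-open genome coordinates with strand,
#'   precursor-relative mature/star spans, sequences, per-condition
#'   proportions and true fold change), `known_precursors`,
#'   `mammal_precursors` (named character catalogs), `other_rna`
#'   (data.frame: name, class, sequence), and `config`.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "mf_sim_config"))
  set.seed(config$seed)
  n <- config$n_known + config$n_conserved + config$n_candidate
  tiers <- rep(c("known_species", "conserved_mammal", "candidate"),
               c(config$n_known, config$n_conserved, config$n_candidate))

  hairpins <- vector("list", n)
  names_mi <- character(n)
  if (n > 0L) {
    ks <- sample(seq(config$mature_length_range[1L],
                     config$mature_length_range[2L]), n, replace = TRUE)
    loops <- sample(seq(config$loop_length_range[1L],
                        config$loop_length_range[2L]), n, replace = TRUE)
    for (i in seq_len(n)) {
      hairpins[[i]] <- plant_hairpin(ks[i], loops[i], config$stem_pairs_min)
      names_mi[i] <- switch(tiers[i],
        known_species = sprintf("ssc-mir-K%03d", i),
        conserved_mammal = sprintf("hsa-mir-C%03d", i),
        candidate = sprintf("cand-mir-%03d", i))
    }
  }

  other <- data.frame(name = character(0), class = character(0),
                      sequence = character(0), stringsAsFactors = FALSE)
  if (config$n_contaminants > 0L) {
    cls <- rep_len(OTHER_RNA_CLASSES, config$n_contaminants)
    lens <- sample(60:120, config$n_contaminants, replace = TRUE)
    other <- data.frame(
      name = sprintf("%s-%02d", cls, seq_len(config$n_contaminants)),
      class = cls,
      sequence = vapply(lens, function(l) random_dna(1L, l), character(1)),
      stringsAsFactors = FALSE)
  }

  # Assemble the genome: features in random order separated by random gaps
  # of at least min_gap (room for 60 nt flank extraction on both sides).
  feat_seqs <- c(vapply(hairpins, `[[`, character(1), "precursor"),
                 other$sequence)
  strands <- c(if (n > 0L) sample(c("+", "-"), n, replace = TRUE),
               rep("+", nrow(other)))
  planted <- ifelse(strands == "-", revcomp(feat_seqs), feat_seqs)
  n_feat <- length(feat_seqs)
  min_gap <- 70L
  slack <- config$genome_length - sum(nchar(feat_seqs)) -
    min_gap * (n_feat + 1L)
  if (slack < 0L)
    stop("genome too short for the requested plantings; increase genome_length")
  ord <- if (n_feat > 0L) sample.int(n_feat) else integer(0)
  cuts <- if (n_feat > 0L) sort(sample.int(slack + 1L, n_feat, replace = TRUE) - 1L)
          else integer(0)
  extras <- diff(c(0L, cuts))
  pieces <- character(2L * n_feat + 1L)
  starts <- integer(n_feat); pos <- 0L
  for (j in seq_len(n_feat)) {
    gap <- min_gap + extras[j]
    pieces[2L * j - 1L] <- random_dna(1L, gap)
    pos <- pos + gap
    starts[ord[j]] <- pos
    pieces[2L * j] <- planted[ord[j]]
    pos <- pos + nchar(planted[ord[j]])
  }
  tail_gap <- config$genome_length - pos
  pieces[2L * n_feat + 1L] <- if (tail_gap > 0L) random_dna(1L, tail_gap) else ""
  genome <- c(chr1 = paste(pieces, collapse = ""))

  # Abundances and per-condition proportions.
  if (!is.null(config$prop_A)) {
    prop_A <- config$prop_A
    prop_B <- config$prop_B
    fc <- ifelse(prop_A > 0, prop_B / prop_A, ifelse(prop_B > 0, Inf, 1))
  } else {
    w <- if (!is.null(config$mirna_weights)) config$mirna_weights
         else if (n > 0L) rlnorm(n, 0, config$abundance_sdlog) else numeric(0)
    mirna_share <- 1 - config$contaminant_fraction - config$oversize_fraction
    prop_A <- if (n > 0L) w / sum(w) * mirna_share else numeric(0)
    fc <- if (!is.null(config$true_fold_changes)) config$true_fold_changes
          else rep(1, n)
    prop_B <- prop_A * fc
    if (sum(prop_B) > 1 - config$oversize_fraction + 1e-9)
      stop("condition-B proportions exceed 1; lower fold changes or miRNA share")
  }

  truth <- data.frame(
    name = names_mi, tier = tiers, chrom = rep("chr1", n),
    start = if (n > 0L) starts[seq_len(n)] else integer(0),
    end = if (n > 0L) starts[seq_len(n)] +
      nchar(feat_seqs[seq_len(n)]) else integer(0),
    strand = if (n > 0L) strands[seq_len(n)] else character(0),
    arm = vapply(hairpins, function(h) h$arm, character(1)),
    mature_start = vapply(hairpins, function(h) h$mature[1L], integer(1)),
    mature_end = vapply(hairpins, function(h) h$mature[2L], integer(1)),
    star_start = vapply(hairpins, function(h) h$star[1L], integer(1)),
    star_end = vapply(hairpins, function(h) h$star[2L], integer(1)),
    precursor = vapply(hairpins, `[[`, character(1), "precursor"),
    prop_A = prop_A, prop_B = prop_B, fold_change = fc,
    stringsAsFactors = FALSE)
  if (n > 0L) {
    truth$mature_seq <- substr(truth$precursor, truth$mature_start + 1L,
                               truth$mature_end)
    truth$star_seq <- substr(truth$precursor, truth$star_start + 1L,
                             truth$star_end)
  } else {
    truth$mature_seq <- character(0); truth$star_seq <- character(0)
  }
  if (nrow(other)) {
    other$start <- starts[n + seq_len(nrow(other))]
    other$end <- other$start + nchar(other$sequence)
  }

  known <- truth$precursor[truth$tier == "known_species"]
  names(known) <- truth$name[truth$tier == "known_species"]
  mammal <- truth$precursor[truth$tier == "conserved_mammal"]
  names(mammal) <- truth$name[truth$tier == "conserved_mammal"]
  if (config$n_decoy_known > 0L) {
    dk <- random_dna(config$n_decoy_known, 80L)
    names(dk) <- sprintf("ssc-mir-D%03d", seq_along(dk))
    known <- c(known, dk)
  }
  if (config$n_decoy_mammal > 0L) {
    dm <- random_dna(config$n_decoy_mammal, 80L)
    names(dm) <- sprintf("mmu-mir-D%03d", seq_along(dm))
    mammal <- c(mammal, dm)
  }

  out <- list(genome = genome, truth = truth, known_precursors = known,
              mammal_precursors = mammal, other_rna = other, config = config)
  class(out) <- "mf_sim_dataset"
  out
}

# Genomic span of the mature arm (0-based half-open, mature sense given by
# the precursor strand).
mature_genome_span <- function(truth_row) {
  plen <- nchar(truth_row$precursor)
  if (truth_row$strand == "+") {
    c(truth_row$start + truth_row$mature_start,
      truth_row$start + truth_row$mature_end)
  } else {
    c(truth_row$start + plen - truth_row$mature_end,
      truth_row$start + plen - truth_row$mature_start)
  }
}

# Extract an isomiR variant sequence from the genome on the mature sense.
# d5 > 0 trims the 5' end; d3 > 0 extends the 3' end (templated).
variant_from_genome <- function(genome, truth_row, d5, d3) {
  span <- mature_genome_span(truth_row)
  if (truth_row$strand == "+") {
    s <- span[1L] + d5; e <- span[2L] + d3
  } else {
    s <- span[1L] - d3; e <- span[2L] - d5
  }
  seq <- substr(genome, s + 1L, e)
  if (truth_row$strand == "-") seq <- revcomp(seq) else seq
}

apply_seq_errors <- function(reads, error_rate) {
  if (error_rate <= 0 || length(reads) == 0L) return(reads)
  n_err <- rbinom(length(reads), nchar(reads), error_rate)
  for (i in which(n_err > 0L)) {
    pos <- sample.int(nchar(reads[i]), n_err[i])
    for (p in pos) {
      old <- substr(reads[i], p, p)
      substr(reads[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
    }
  }
  reads
}

#' Simulate the two small RNA libraries from a planted genome
#'
#' Reads per library are drawn multinomially across mature miRNAs (split
#' over isomiR variants per the configured profile, with the unmodified
#' mature the most probable variant), star arms, contaminant-feature
#' fragments (18-30 nt), and an oversize tail (41-45 nt genomic
#' fragments). Per-base substitution errors are then applied. The total
#' read count per library equals the configured depth exactly.
#'
#' @param dataset An `mf_sim_dataset` from [generate_genome()].
#' @param config Simulation configuration (defaults to the dataset's own).
#'
#' @return List of class `mf_sim_libraries` with `reads` (named list of
#'   named character vectors, one per library) and `expected_counts`
#'   (data.frame of exact expected mature and star read counts per miRNA
#'   per library).
#' @export
simulate_libraries <- function(dataset, config = dataset$config) {
  stopifnot(inherits(dataset, "mf_sim_dataset"))
  set.seed(config$seed + 1L)
  truth <- dataset$truth
  n <- nrow(truth)
  libs <- names(config$library_depths)
  prof <- config$isomir_profile
  genome <- dataset$genome[[1L]]

  props <- list(truth$prop_A, truth$prop_B)
  names(props) <- libs

  # Pre-compute variant sequences per miRNA (shared across libraries).
  variant_seqs <- lapply(seq_len(n), function(i) {
    vapply(seq_len(nrow(prof)), function(v) {
      variant_from_genome(genome, truth[i, ], prof$d5[v], prof$d3[v])
    }, character(1))
  })

  reads <- list()
  expected <- list()
  for (lib in libs) {
    depth <- config$library_depths[[lib]]
    p <- props[[lib]]
    w_mature <- p * (1 - config$star_fraction)
    w_star <- p * config$star_fraction
    w_over <- config$oversize_fraction
    w_cont_total <- max(0, 1 - sum(p) - w_over)
    n_cont <- nrow(dataset$other_rna)
    w_cont <- if (n_cont > 0L) rep(w_cont_total / n_cont, n_cont) else numeric(0)
    weights <- c(w_mature, w_star, w_cont, w_over)
    counts <- as.vector(rmultinom(1L, depth, weights))
    c_mature <- counts[seq_len(n)]
    c_star <- counts[n + seq_len(n)]
    c_cont <- if (n_cont > 0L) counts[2L * n + seq_len(n_cont)] else integer(0)
    c_over <- counts[length(counts)]

    chunks <- list()
    for (i in seq_len(n)) {
      if (c_mature[i] > 0L) {
        vc <- as.vector(rmultinom(1L, c_mature[i], prof$prob))
        vseq <- rep(variant_seqs[[i]], vc)
        subst <- rep(prof$subst == 1L, vc)
        if (any(subst)) {
          idx <- which(subst)
          pos <- ceiling(runif(length(idx)) * nchar(vseq[idx]))
          for (j in seq_along(idx)) {
            k <- idx[j]
            old <- substr(vseq[k], pos[j], pos[j])
            substr(vseq[k], pos[j], pos[j]) <-
              sample(setdiff(c("A", "C", "G", "T"), old), 1L)
          }
        }
        chunks[[length(chunks) + 1L]] <- vseq
      }
      if (c_star[i] > 0L)
        chunks[[length(chunks) + 1L]] <- rep(truth$star_seq[i], c_star[i])
    }
    if (n_cont > 0L) {
      for (f in seq_len(n_cont)) {
        if (c_cont[f] == 0L) next
        feat <- dataset$other_rna$sequence[f]
        flen <- sample(18:30, c_cont[f], replace = TRUE)
        flen <- pmin(flen, nchar(feat))
        fstart <- ceiling(runif(c_cont[f]) * (nchar(feat) - flen + 1L))
        chunks[[length(chunks) + 1L]] <-
          substring(feat, fstart, fstart + flen - 1L)
      }
    }
    if (c_over > 0L) {
      olen <- sample(41:45, c_over, replace = TRUE)
      ostart <- ceiling(runif(c_over) * (nchar(genome) - max(olen)))
      chunks[[length(chunks) + 1L]] <-
        substring(genome, ostart, ostart + olen - 1L)
    }

    lib_reads <- unlist(chunks, use.names = FALSE)
    if (is.null(lib_reads)) lib_reads <- character(0)
    lib_reads <- apply_seq_errors(lib_reads, config$error_rate)
    lib_reads <- sample(lib_reads)
    names(lib_reads) <- sprintf("%s_%07d", lib, seq_along(lib_reads))
    reads[[lib]] <- lib_reads
    expected[[lib]] <- data.frame(
      name = truth$name,
      expected_mature = depth * w_mature,
      expected_star = depth * w_star, stringsAsFactors = FALSE)
  }

  exp_tab <- data.frame(name = truth$name, stringsAsFactors = FALSE)
  for (lib in libs) {
    exp_tab[[paste0("expected_", lib)]] <- expected[[lib]]$expected_mature
    exp_tab[[paste0("expected_star_", lib)]] <- expected[[lib]]$expected_star
  }
  out <- list(reads = reads, expected_counts = exp_tab)
  class(out) <- "mf_sim_libraries"
  out
}
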