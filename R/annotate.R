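# Three-tier miRNA annotation: other-RNA removal, full-length tag mapping
# (substitutions only), sequential tier assignment (same-species catalog ->
# other-mammal catalog -> genome-anchored novel candidates with predicted
# hairpins from 60 nt genomic flanks), and miRNA* detection by duplex
# geometry. Mapping is exact/near-exact full-length matching, the standard
# small RNA convention for 10-40 nt tags.

#' Map tags to target sequences by full-length matching
#'
#' Reports every occurrence of each tag in each target with at most
#' `max_mismatch` substitutions over the full tag length (no indels).
#' With `both_strands = TRUE` the reverse complement of each tag is also
#' searched and minus-strand hits are reported in plus-strand coordinates.
#'
#' @param tags Character vector of tag sequences, or a tag data.frame with
#'   a `sequence` column.
#' @param targets Named character vector of target sequences (precursors,
#'   genome contigs, or other-RNA features).
#' @param max_mismatch Maximum substitutions (default 1).
#' @param both_strands Also search the minus strand (default FALSE; use
#'   TRUE for genome targets).
#'
#' @return Data.frame with columns `tag`, `target`, `start`, `end`
#'   (0-based half-open in target coordinates), `strand`, `mismatches`.
#' @export
map_tags <- function(tags, targets, max_mismatch = 1L, both_strands = FALSE) {
  seqs <- if (is.data.frame(tags)) tags$sequence else tags
  seqs <- unique(to_dna(seqs))
  seqs <- seqs[!grepl("N", seqs, fixed = TRUE)]
  empty <- data.frame(tag = character(0), target = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0),
                      stringsAsFactors = FALSE)
  if (!length(seqs) || !length(targets)) return(empty)
  targets <- to_dna(targets)
  stopifnot(!is.null(names(targets)))
  strands <- if (both_strands) c("+", "-") else "+"

  # Seed-and-verify: each pattern is split into max_mismatch + 1 pieces; by
  # pigeonhole an occurrence with <= max_mismatch substitutions contains at
  # least one piece exactly. Exact piece hits come from a PDict scan;
  # candidate placements are then verified by Hamming distance.
  k <- as.integer(max_mismatch) + 1L
  patt <- unlist(lapply(strands, function(s) {
    p <- if (s == "+") seqs else revcomp(seqs)
    names(p) <- seqs
    p
  }))
  patt_strand <- rep(strands, each = length(seqs))
  pieces <- list(); piece_pat <- integer(0); piece_off <- integer(0)
  for (i in seq_along(patt)) {
    L <- nchar(patt[i])
    bounds <- unique(round(seq(0L, L, length.out = k + 1L)))
    for (j in seq_len(length(bounds) - 1L)) {
      pieces[[length(pieces) + 1L]] <-
        substr(patt[i], bounds[j] + 1L, bounds[j + 1L])
      piece_pat <- c(piece_pat, i)
      piece_off <- c(piece_off, bounds[j])
    }
  }
  piece_seq <- unname(unlist(pieces))
  # PDict requires constant-width patterns: build one dictionary per piece
  # width and scan each against every target.
  width_groups <- split(seq_along(piece_seq), nchar(piece_seq))
  pdicts <- lapply(width_groups, function(idx)
    Biostrings::PDict(Biostrings::DNAStringSet(piece_seq[idx])))

  rows <- list()
  for (t in seq_along(targets)) {
    subj <- Biostrings::DNAString(targets[[t]])
    hit_piece <- integer(0); hit_start <- integer(0)
    for (g in seq_along(pdicts)) {
      m <- Biostrings::matchPDict(pdicts[[g]], subj)
      si <- Biostrings::startIndex(m)
      hp <- rep(width_groups[[g]], lengths(si))
      if (!length(hp)) next
      hit_piece <- c(hit_piece, hp)
      hit_start <- c(hit_start, unlist(si, use.names = FALSE))
    }
    if (!length(hit_piece)) next
    cand <- data.frame(pat = piece_pat[hit_piece],
                       start = hit_start - piece_off[hit_piece])
    cand <- unique(cand)
    L <- nchar(patt)[cand$pat]
    ok <- cand$start >= 1L & cand$start + L - 1L <= length(subj)
    cand <- cand[ok, , drop = FALSE]; L <- L[ok]
    if (!nrow(cand)) next
    mm <- integer(nrow(cand))
    for (p in unique(cand$pat)) {
      idx <- which(cand$pat == p)
      mm[idx] <- Biostrings::neditStartingAt(
        Biostrings::DNAString(patt[[p]]), subj,
        starting.at = cand$start[idx], with.indels = FALSE)
    }
    keep <- mm <= max_mismatch
    if (!any(keep)) next
    cand <- cand[keep, , drop = FALSE]; L <- L[keep]; mm <- mm[keep]
    rows[[length(rows) + 1L]] <- data.frame(
      tag = names(patt)[cand$pat], target = names(targets)[t],
      start = cand$start - 1L, end = cand$start - 1L + L,
      strand = patt_strand[cand$pat], mismatches = as.integer(mm),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$tag, out$target, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove tags matching other RNA classes
#'
#' Tags aligning to any feature of the other-RNA set (rRNA, tRNA, snRNA,
#' snoRNA, mRNA, repeats) are eliminated before miRNA annotation; the read
#' fraction removed per class is reported.
#'
#' @param tags Tag data.frame with per-library count columns.
#' @param other_rna Data.frame with columns `name`, `class`, `sequence`.
#' @param max_mismatch Maximum substitutions for a tag/feature match
#'   (default 0).
#'
#' @return List with `tags` (clean tags), `removed` (removed tags with the
#'   matched class), and `class_proportions` (data.frame: class, library,
#'   reads, fraction of input reads).
#' @export
remove_other_rna <- function(tags, other_rna, max_mismatch = 0L) {
  input_totals <- tag_read_totals(tags)
  if (is.null(other_rna) || nrow(other_rna) == 0L) {
    warning("other-RNA set is empty; no tags removed")
    props <- data.frame(class = character(0), library = character(0),
                        reads = numeric(0), fraction = numeric(0))
    return(list(tags = tags, removed = tags[0L, , drop = FALSE],
                class_proportions = props))
  }
  feats <- other_rna$sequence
  names(feats) <- other_rna$name
  aln <- map_tags(tags, feats, max_mismatch = max_mismatch)
  hit <- tags$sequence %in% aln$tag
  removed <- tags[hit, , drop = FALSE]
  if (nrow(removed)) {
    first_hit <- aln[!duplicated(aln$tag), ]
    cls <- other_rna$class[match(first_hit$target, other_rna$name)]
    removed$class <- cls[match(removed$sequence, first_hit$tag)]
  } else {
    removed$class <- character(0)
  }
  cc <- count_cols(tags)
  props <- do.call(rbind, lapply(cc, function(col) {
    lib <- sub("^count_", "", col)
    reads <- tapply(removed[[col]], removed$class, sum)
    if (is.null(reads) || !length(reads)) {
      return(data.frame(class = character(0), library = character(0),
                        reads = numeric(0), fraction = numeric(0)))
    }
    data.frame(class = names(reads), library = lib,
               reads = as.numeric(reads),
               fraction = as.numeric(reads) / input_totals[[lib]],
               stringsAsFactors = FALSE)
  }))
  rownames(props) <- NULL
  list(tags = tags[!hit, , drop = FALSE], removed = removed,
       class_proportions = props)
}

#' Extract a candidate precursor window around a genomic locus
#'
#' Returns the locus sequence extended by `flank` nucleotides on either
#' side (clipped at contig bounds), reverse-complemented for minus-strand
#' loci so the window is on the mature sense, with the mature span
#' translated into window coordinates.
#'
#' @param genome Named character vector of contig sequences.
#' @param locus List or one-row data.frame with `chrom`, `start`, `end`
#'   (0-based half-open), `strand`.
#' @param flank Flank length in nt (default 60).
#'
#' @return List with `sequence`, `chrom`, `window_start`, `window_end`
#'   (0-based half-open genome coordinates of the window), `strand`, and
#'   `mature_span` (0-based half-open within the window, mature sense).
#' @export
extract_flanks <- function(genome, locus, flank = 60L) {
  chrom <- locus$chrom
  if (!chrom %in% names(genome)) stop("unknown contig: ", chrom)
  contig <- genome[[chrom]]
  n <- nchar(contig)
  if (locus$start < 0L || locus$end > n || locus$start >= locus$end)
    stop("locus outside contig bounds")
  ws <- max(0L, locus$start - flank)
  we <- min(n, locus$end + flank)
  seq <- substr(contig, ws + 1L, we)
  if (locus$strand == "-") {
    seq <- revcomp(seq)
    mature <- c(we - locus$end, we - locus$start)
  } else {
    mature <- c(locus$start - ws, locus$end - ws)
  }
  list(sequence = seq, chrom = chrom, window_start = ws, window_end = we,
       strand = locus$strand, mature_span = as.integer(mature))
}

#' Test whether a tag is the miRNA* of a mature miRNA
#'
#' A tag is accepted as the star when it lies on the opposite arm of the
#' same hairpin (its span base-pairs with the mature span) and the
#' mature/star duplex shows 3' overhangs of at most `max_overhang`
#' nucleotides on both strands, the geometry left by Drosha/Dicer
#' processing.
#'
#' The duplex is assessed directly from sequence complementarity between
#' the two spans rather than from the realized pairs of the global
#' minimum-free-energy structure: a weighted Nussinov optimum is not
#' unique, and score ties can realize a structure in which a genuine
#' mature/star duplex is absent even though the two arms are near-perfect
#' reverse complements. For every antiparallel register `R` (a pair
#' `(i, j)` in a duplex satisfies `i + j = R`) whose implied 3' overhangs
#' on both strands lie within `[0, max_overhang]`, the fraction of
#' complementary positions (Watson-Crick or GU) between the spans is
#' computed; the tag is the star when the best such register pairs at
#' least `min_paired_fraction` of the shorter span. Overlapping spans
#' (same arm) are never a mature/star pair.
#'
#' @param structure An `mf_structure` of the precursor (from [fold()]),
#'   or the precursor sequence itself as a character scalar.
#' @param mature_span,tag_span 0-based half-open intervals within the
#'   folded sequence.
#' @param max_overhang Maximum 3' overhang in nt (default 4).
#' @param min_paired_fraction Minimum complementary fraction of the
#'   shorter span in the best admissible register (default 0.6).
#' @return TRUE when the tag satisfies the star criterion.
#' @export
detect_star <- function(structure, mature_span, tag_span, max_overhang = 4L,
                        min_paired_fraction = 0.6) {
  seq <- if (is.character(structure)) structure else structure$sequence
  if (max(mature_span[1L], tag_span[1L]) <
        min(mature_span[2L], tag_span[2L])) return(FALSE)  # same arm
  bases <- strsplit(to_dna(seq), "")[[1L]]
  comp <- function(a, b) {
    (a == "A" & b == "T") | (a == "T" & b == "A") |
      (a == "G" & b == "C") | (a == "C" & b == "G") |
      (a == "G" & b == "T") | (a == "T" & b == "G")
  }
  ms <- mature_span[1L]; me <- mature_span[2L]
  ts <- tag_span[1L]; te <- tag_span[2L]
  # register bounds from the two 3' overhang constraints:
  #   o_mature = (me - 1) - (R - ts) in [0, max_overhang]
  #   o_tag    = (te - 1) - (R - ms) in [0, max_overhang]
  lo <- max(me - 1L + ts - max_overhang, te - 1L + ms - max_overhang)
  hi <- min(me - 1L + ts, te - 1L + ms)
  if (lo > hi) return(FALSE)
  denom <- min(me - ms, te - ts)
  best <- 0
  for (R in lo:hi) {
    i1 <- max(ms, R - (te - 1L)); i2 <- min(me - 1L, R - ts)
    if (i1 > i2) next
    i <- i1:i2
    j <- R - i
    frac <- sum(comp(bases[i + 1L], bases[j + 1L])) / denom
    if (frac > best) best <- frac
  }
  best >= min_paired_fraction
}

# Greedy clustering of aligned tags into mature loci: process tags by
# decreasing total count; each unassigned tag seeds a cluster collecting
# tags whose alignment on the same target starts and ends within
# `slop` nt of the seed.
cluster_alignments <- function(aln, tag_counts, slop = 3L) {
  aln$total <- tag_counts[aln$tag]
  ord <- order(-aln$total, aln$tag)
  aln <- aln[ord, , drop = FALSE]
  assigned <- character(0)
  clusters <- list()
  for (r in seq_len(nrow(aln))) {
    tag <- aln$tag[r]
    if (tag %in% assigned) next
    seed_hits <- aln[aln$tag == tag, , drop = FALSE]
    member_rows <- rep(FALSE, nrow(aln))
    for (h in seq_len(nrow(seed_hits))) {
      member_rows <- member_rows |
        (aln$target == seed_hits$target[h] &
           aln$strand == seed_hits$strand[h] &
           abs(aln$start - seed_hits$start[h]) <= slop &
           abs(aln$end - seed_hits$end[h]) <= slop)
    }
    members <- setdiff(unique(aln$tag[member_rows]), assigned)
    assigned <- c(assigned, members)
    clusters[[length(clusters) + 1L]] <-
      list(seed = tag, seed_hits = seed_hits, members = members)
  }
  clusters
}

default_hairpin_thresholds <- function() {
  list(min_stem_pairs = 14L, min_paired_fraction = 0.6, min_loop_length = 3L)
}

#' Assign mappable tags to the three annotation tiers
#'
#' Tier assignment is sequential and exclusive: tags matching same-species
#' precursors are tier `known_species`; remaining tags matching
#' other-mammal precursors are tier `conserved_mammal`; remaining tags
#' longer than 18 nt with genome hits proceed to candidate calling, where a
#' predicted hairpin over the locus plus 60 nt flanks must pass
#' [is_valid_hairpin()]. Tags are clustered into mature loci (isomiR slop
#' of `slop` nt); within each precursor the most abundant cluster is the
#' mature and opposite-arm clusters satisfying the duplex-overhang
#' criterion are flagged as miRNA*.
#'
#' @param tags Mappable tag data.frame (other RNA already removed).
#' @param known_precursors,mammal_precursors Named character catalogs.
#' @param genome Named character vector of contigs, or NULL (candidates
#'   skipped with a warning).
#' @param max_mismatch Maximum substitutions for mapping (default 1).
#' @param flank Flank length for candidate windows (default 60).
#' @param min_candidate_len Minimum tag length for candidate calling;
#'   tags of this length or shorter are excluded (default 18, i.e. only
#'   tags longer than 18 nt are used).
#' @param slop Mature-locus clustering slop in nt (default 3).
#' @param thresholds Hairpin-acceptance thresholds (list with
#'   `min_stem_pairs`, `min_paired_fraction`, `min_loop_length`).
#' @param weights Pairing weights passed to [fold()].
#'
#' @return List of class `mf_annotation` with `annotations` (one row per
#'   mature or star miRNA: name, tier, precursor id, loci, arm, is_star,
#'   representative tag, per-library counts), `members` (tag-to-annotation
#'   assignment with counts), and `tier_table` (miRNA/precursor/star counts
#'   per tier).
#' @export
classify_tiers <- function(tags, known_precursors, mammal_precursors,
                           genome = NULL, max_mismatch = 1L, flank = 60L,
                           min_candidate_len = 18L, slop = 3L,
                           thresholds = default_hairpin_thresholds(),
                           weights = c(GC = 3, AU = 2, GU = 1)) {
  cc <- count_cols(tags)
  tag_counts <- rowSums(tags[, cc, drop = FALSE])
  names(tag_counts) <- tags$sequence

  annotations <- list()
  members <- list()

  precursor_tier <- function(aln, tier, catalog) {
    if (nrow(aln) == 0L) return(invisible(NULL))
    for (prec in unique(aln$target)) {
      prec_seq <- catalog[[prec]]
      struct <- fold(prec_seq, weights = weights)
      sub <- aln[aln$target == prec, , drop = FALSE]
      clusters <- cluster_alignments(sub, tag_counts, slop)
      # order clusters by abundance; the top cluster is the mature
      ctot <- vapply(clusters, function(cl) sum(tag_counts[cl$members]),
                     numeric(1))
      clusters <- clusters[order(-ctot)]
      mature_span <- NULL
      mature_name <- NA_character_
      arm_seen <- character(0)
      for (ci in seq_along(clusters)) {
        cl <- clusters[[ci]]
        span <- c(cl$seed_hits$start[1L], cl$seed_hits$end[1L])
        feats <- hairpin_features(struct, span)
        is_star <- FALSE
        if (!is.null(mature_span))
          is_star <- detect_star(struct, mature_span, span)
        arm <- feats$arm
        suffix <- if (arm %in% arm_seen) sprintf("-%s.%d", arm, ci)
                  else paste0("-", arm)
        arm_seen <- c(arm_seen, arm)
        nm <- paste0(prec, suffix, if (is_star) "*" else "")
        if (is.null(mature_span)) {
          mature_span <- span
          mature_name <- nm
        }
        annotations[[length(annotations) + 1L]] <<- list(
          name = nm, tier = tier, precursor_id = prec,
          chrom = NA_character_, loci = NA_character_, n_loci = 1L,
          arm = arm, is_star = is_star,
          mature_partner = if (is_star) mature_name else NA_character_,
          representative_tag = cl$seed,
          precursor_seq = prec_seq,
          mature_start = span[1L], mature_end = span[2L],
          members = cl$members)
      }
    }
    invisible(NULL)
  }

  aln_known <- map_tags(tags, known_precursors, max_mismatch)
  precursor_tier(aln_known, "known_species", known_precursors)
  used <- unique(aln_known$tag)

  rest <- tags[!tags$sequence %in% used, , drop = FALSE]
  aln_mammal <- map_tags(rest, mammal_precursors, max_mismatch)
  precursor_tier(aln_mammal, "conserved_mammal", mammal_precursors)
  used <- c(used, unique(aln_mammal$tag))

  rest <- tags[!tags$sequence %in% used, , drop = FALSE]
  if (is.null(genome)) {
    if (nrow(rest)) warning("no genome supplied; candidate calling skipped")
  } else {
    cand_tags <- rest[rest$length > min_candidate_len, , drop = FALSE]
    if (nrow(cand_tags)) {
      aln_g <- map_tags(cand_tags, genome, max_mismatch, both_strands = TRUE)
      cand_anno <- call_candidates(aln_g, genome, tag_counts, flank = flank,
                                   slop = slop, thresholds = thresholds,
                                   weights = weights)
      for (a in cand_anno) annotations[[length(annotations) + 1L]] <- a
    }
  }

  build_annotation_result(annotations, tags, cc)
}

#' Call novel candidate miRNAs from genome-anchored tag clusters
#'
#' Clusters genome alignments of unannotated tags into loci, extracts a
#' window of the locus plus flanking sequence for each locus, folds it, and
#' emits a candidate miRNA when the best-scoring window passes
#' [is_valid_hairpin()]. A tag cluster hitting several loci yields one
#' miRNA with multiple loci. Opposite-arm clusters within the same window
#' that satisfy the duplex-overhang criterion are flagged as miRNA*.
#'
#' @param aln Genome alignments of candidate tags (from [map_tags()]).
#' @param genome Named character vector of contigs.
#' @param tag_counts Named numeric of total counts per tag sequence.
#' @param flank,slop,thresholds,weights As in [classify_tiers()].
#'
#' @return List of annotation records (internal form consumed by
#'   [classify_tiers()]).
#' @export
call_candidates <- function(aln, genome, tag_counts, flank = 60L, slop = 3L,
                            thresholds = default_hairpin_thresholds(),
                            weights = c(GC = 3, AU = 2, GU = 1)) {
  out <- list()
  if (nrow(aln) == 0L) return(out)
  clusters <- cluster_alignments(aln, tag_counts, slop)

  # Fold the window of every locus of every cluster; keep per-cluster best.
  evals <- lapply(clusters, function(cl) {
    loci <- cl$seed_hits
    wins <- lapply(seq_len(nrow(loci)), function(h) {
      locus <- list(chrom = loci$target[h], start = loci$start[h],
                    end = loci$end[h], strand = loci$strand[h])
      win <- extract_flanks(genome, locus, flank)
      win$structure <- fold(win$sequence, weights = weights)
      win$features <- hairpin_features(win$structure, win$mature_span)
      win$valid <- do.call(is_valid_hairpin,
                           c(list(win$features), thresholds))$valid
      win
    })
    scores <- vapply(wins, function(w) w$structure$score, numeric(1))
    best <- which.max(scores)
    list(cluster = cl, windows = wins, best = wins[[best]])
  })

  keep <- vapply(evals, function(e) e$best$valid, logical(1))
  evals <- evals[keep]
  if (!length(evals)) return(out)

  # Group accepted clusters sharing a hairpin window (same contig/strand,
  # overlapping windows): the more abundant cluster is the mature, the
  # other is tested as its star.
  n_ev <- length(evals)
  tot <- vapply(evals, function(e) sum(tag_counts[e$cluster$members]),
                numeric(1))
  ord <- order(-tot)
  star_of <- rep(NA_integer_, n_ev)
  for (a in seq_len(n_ev)) {
    for (b in seq_len(n_ev)) {
      ea <- evals[[ord[a]]]; eb <- evals[[ord[b]]]
      if (a >= b || !is.na(star_of[ord[b]]) || !is.na(star_of[ord[a]])) next
      # A genuine star tag lies on the same strand of the same hairpin as
      # its mature, but each tag may also hit the opposite strand of the
      # locus (a tag and its near-reverse-complement star mirror each
      # other), so every same-strand pair of locus windows is tested, not
      # just the best-scoring window of each cluster.
      found <- FALSE
      for (wa in ea$windows) {
        if (found) break
        for (wb in eb$windows) {
          if (wa$chrom != wb$chrom || wa$strand != wb$strand) next
          if (wb$window_start >= wa$window_end ||
              wa$window_start >= wb$window_end) next
          # translate b's mature span into a's window coordinates
          if (wa$strand == "+") {
            gs <- wb$window_start + wb$mature_span[1L]
            ge <- wb$window_start + wb$mature_span[2L]
            span_b <- c(gs - wa$window_start, ge - wa$window_start)
          } else {
            gs <- wb$window_end - wb$mature_span[2L]
            ge <- wb$window_end - wb$mature_span[1L]
            span_b <- c(wa$window_end - ge, wa$window_end - gs)
          }
          if (span_b[1L] < 0L || span_b[2L] > nchar(wa$sequence)) next
          if (detect_star(wa$structure, wa$mature_span, span_b)) {
            found <- TRUE
            break
          }
        }
      }
      if (found) star_of[ord[b]] <- ord[a]
    }
  }

  for (e in seq_len(n_ev)) {
    ev <- evals[[e]]
    best <- ev$best
    loci_str <- paste(sprintf("%s:%d-%d(%s)", ev$cluster$seed_hits$target,
                              ev$cluster$seed_hits$start,
                              ev$cluster$seed_hits$end,
                              ev$cluster$seed_hits$strand), collapse = ",")
    is_star <- !is.na(star_of[e])
    base <- sprintf("cand-%s:%d-%d(%s)", best$chrom,
                    best$window_start + best$mature_span[1L],
                    best$window_start + best$mature_span[2L], best$strand)
    partner <- if (is_star) {
      m <- evals[[star_of[e]]]$best
      sprintf("cand-%s:%d-%d(%s)", m$chrom,
              m$window_start + m$mature_span[1L],
              m$window_start + m$mature_span[2L], m$strand)
    } else NA_character_
    out[[length(out) + 1L]] <- list(
      name = paste0(base, if (is_star) "*" else ""),
      tier = "candidate",
      precursor_id = sprintf("%s:%d-%d(%s)", best$chrom, best$window_start,
                             best$window_end, best$strand),
      chrom = best$chrom, loci = loci_str,
      n_loci = nrow(ev$cluster$seed_hits),
      arm = best$features$arm, is_star = is_star,
      mature_partner = partner,
      representative_tag = ev$cluster$seed,
      precursor_seq = best$sequence,
      mature_start = best$mature_span[1L], mature_end = best$mature_span[2L],
      members = ev$cluster$members)
  }
  out
}

# Assemble the annotation records into the exported result tables.
build_annotation_result <- function(annotations, tags, cc) {
  if (!length(annotations)) {
    anno_df <- data.frame(name = character(0), tier = character(0),
                          precursor_id = character(0), loci = character(0),
                          n_loci = integer(0), arm = character(0),
                          is_star = logical(0), mature_partner = character(0),
                          representative_tag = character(0),
                          precursor_seq = character(0),
                          mature_start = integer(0), mature_end = integer(0),
                          stringsAsFactors = FALSE)
    for (col in cc) anno_df[[col]] <- numeric(0)
    res <- list(annotations = anno_df,
                members = data.frame(annotation = character(0),
                                     sequence = character(0)),
                tier_table = tier_table_from(anno_df, cc))
    class(res) <- "mf_annotation"
    return(res)
  }
  anno_df <- do.call(rbind, lapply(annotations, function(a) {
    data.frame(name = a$name, tier = a$tier, precursor_id = a$precursor_id,
               loci = a$loci, n_loci = a$n_loci, arm = a$arm,
               is_star = a$is_star, mature_partner = a$mature_partner,
               representative_tag = a$representative_tag,
               precursor_seq = a$precursor_seq,
               mature_start = a$mature_start, mature_end = a$mature_end,
               stringsAsFactors = FALSE)
  }))
  member_df <- do.call(rbind, lapply(annotations, function(a) {
    data.frame(annotation = a$name, sequence = a$members,
               stringsAsFactors = FALSE)
  }))
  member_df <- merge(member_df, tags, by = "sequence", sort = FALSE)
  for (col in cc) {
    agg <- tapply(member_df[[col]], member_df$annotation, sum)
    anno_df[[col]] <- as.numeric(agg[anno_df$name])
    anno_df[[col]][is.na(anno_df[[col]])] <- 0
  }
  rownames(anno_df) <- NULL
  res <- list(annotations = anno_df, members = member_df,
              tier_table = tier_table_from(anno_df, cc))
  class(res) <- "mf_annotation"
  res
}

# Table 1-shaped summary: miRNAs (non-star), precursors, stars per tier.
tier_table_from <- function(anno_df, cc) {
  tiers <- c("known_species", "conserved_mammal", "candidate")
  rows <- lapply(tiers, function(t) {
    sub <- anno_df[anno_df$tier == t, , drop = FALSE]
    row <- data.frame(tier = t,
                      n_mirna = sum(!sub$is_star),
                      n_precursor = length(unique(sub$precursor_id)),
                      n_star = sum(sub$is_star), stringsAsFactors = FALSE)
    for (col in cc) row[[col]] <- sum(sub[[col]][!sub$is_star])
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
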