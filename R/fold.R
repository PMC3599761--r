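#' Predict a hairpin secondary structure by weighted base-pair maximization
#'
#' Computes a maximum-weight, non-crossing (pseudoknot-free) set of base
#' pairs for an RNA/DNA sequence under a simple pairing weight scheme
#' (default GC = 3, AU = 2, GU = 1) with a minimum hairpin-loop constraint.
#' This is a Nussinov-style dynamic program: it maximizes weighted pairing
#' rather than nearest-neighbor free energy, which makes it self-contained
#' and exactly checkable against exhaustive enumeration. An external
#' thermodynamic folder can be substituted via the `folder` argument of
#' [call_candidates()].
#'
#' @param sequence Single character string over A/C/G/T/U (case
#'   insensitive). T and U are equivalent.
#' @param min_loop Minimum number of unpaired bases enclosed by any pair
#'   (steric hairpin-loop minimum), default 3.
#' @param weights Named numeric vector with elements `GC`, `AU`, `GU`
#'   giving the score contributed by each pair type.
#'
#' @return An object of class `mf_structure`: a list with `sequence`,
#'   `dot_bracket` (string over "()." of the same length), `pairs`
#'   (two-column integer matrix of 0-based (i, j) indices, i < j), and
#'   `score` (total pairing weight).
#'
#' @examples
#' fold("GGGAAACCC", weights = c(GC = 1, AU = 1, GU = 1))
#' @export
fold <- function(sequence, min_loop = 3,
                 weights = c(GC = 3, AU = 2, GU = 1)) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  enc <- encode_bases(sequence)
  if (length(enc) > 400L)
    stop("sequence longer than 400 nt; fold() targets precursor-scale windows")
  res <- .nussinov_fold(enc, as.integer(min_loop),
                        weights[["GC"]], weights[["AU"]], weights[["GU"]])
  pairs <- res$pairs
  if (nrow(pairs) > 1L) pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  db <- rep(".", length(enc))
  if (nrow(pairs)) {
    db[pairs[, 1L] + 1L] <- "("
    db[pairs[, 2L] + 1L] <- ")"
  }
  structure(
    list(sequence = toupper(gsub("U", "T", toupper(sequence))),
         dot_bracket = paste(db, collapse = ""),
         pairs = pairs,
         score = res$score),
    class = "mf_structure")
}

#' @export
print.mf_structure <- function(x, ...) {
  cat(x$sequence, "\n", x$dot_bracket, "\n",
      sprintf("score %.1f, %d pairs", x$score, nrow(x$pairs)), "\n", sep = "")
  invisible(x)
}

# Map A/C/G/T/U characters to integer codes 0..3 (U -> T code 3).
encode_bases <- function(sequence) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  code <- match(chars, c("A", "C", "G", "T", "U")) - 1L
  code[code == 4L] <- 3L
  if (anyNA(code))
    stop("invalid alphabet: sequence must contain only A/C/G/T/U")
  code
}

#' Exhaustive-search optimum pairing score (reference implementation)
#'
#' Enumerates every valid non-crossing pairing (respecting the minimum
#' loop) by recursion and returns the maximum total weight. Exponential in
#' sequence length; intended as an independent reference for validating
#' [fold()] on short sequences (length <= 12 or so), not for production
#' use.
#'
#' @inheritParams fold
#' @return The optimal pairing score.
#' @export
fold_exhaustive <- function(sequence, min_loop = 3,
                            weights = c(GC = 3, AU = 2, GU = 1)) {
  enc <- encode_bases(sequence)
  pair_w <- function(a, b) {
    key <- paste(sort(c(a, b)), collapse = "")
    switch(key, "12" = weights[["GC"]], "03" = weights[["AU"]],
           "23" = weights[["GU"]], -1)
  }
  n <- length(enc)
  best <- function(idx) {
    if (length(idx) == 0L) return(0)
    i <- idx[1L]
    # i unpaired
    top <- best(idx[-1L])
    for (jpos in seq_along(idx)[-1L]) {
      j <- idx[jpos]
      if (j - i - 1L < min_loop) next
      w <- pair_w(enc[i], enc[j])
      if (w < 0) next
      inside <- idx[idx > i & idx < j]
      outside <- idx[idx > j]
      cand <- w + best(inside) + best(outside)
      if (cand > top) top <- cand
    }
    top
  }
  best(seq_len(n))
}

#' Summarize hairpin geometry of a folded precursor window
#'
#' Derives the features used to accept or reject a candidate pre-miRNA
#' hairpin: the length of the longest stem (the longest mutually nested
#' chain of base pairs, allowing internal bulges), the hairpin loop length
#' enclosed by that stem, the fraction of mature-arm bases that are paired,
#' which arm of the hairpin carries the mature sequence, and a weighted
#' pairing score with sign flipped so that more stable structures are more
#' negative (a stand-in scale for folding free energy).
#'
#' @param structure An `mf_structure` from [fold()].
#' @param mature_span Integer length-2 vector, 0-based half-open interval
#'   of the mature miRNA within the folded sequence.
#'
#' @return A list of class `mf_hairpin_features`: `stem_pairs`,
#'   `loop_length`, `paired_fraction_of_mature`, `arm` (one of "5p", "3p",
#'   "loop_spanning"), `free_energy_proxy`, and `stem` (the pair matrix of
#'   the longest stem).
#' @export
hairpin_features <- function(structure, mature_span) {
  stopifnot(inherits(structure, "mf_structure"))
  n <- nchar(structure$sequence)
  ms <- as.integer(mature_span[1L]); me <- as.integer(mature_span[2L])
  if (ms < 0L || me > n || ms >= me)
    stop("mature span outside sequence")
  pairs <- structure$pairs

  if (nrow(pairs) == 0L) {
    out <- list(stem_pairs = 0L, loop_length = NA_integer_,
                paired_fraction_of_mature = 0,
                arm = "loop_spanning",
                free_energy_proxy = 0,
                stem = pairs)
    class(out) <- "mf_hairpin_features"
    return(out)
  }

  stem <- longest_stem(pairs)
  inner <- stem[nrow(stem), ]                 # innermost pair of the stem
  loop_length <- inner[2L] - inner[1L] - 1L
  mid <- (inner[1L] + inner[2L]) / 2

  paired_pos <- c(pairs[, 1L], pairs[, 2L])
  mature_pos <- seq.int(ms, me - 1L)
  paired_frac <- mean(mature_pos %in% paired_pos)

  arm <- if (me - 1L <= mid) "5p" else if (ms >= mid) "3p" else "loop_spanning"

  out <- list(stem_pairs = nrow(stem),
              loop_length = as.integer(loop_length),
              paired_fraction_of_mature = paired_frac,
              arm = arm,
              free_energy_proxy = -structure$score,
              stem = stem)
  class(out) <- "mf_hairpin_features"
  out
}

# Longest stem: the longest chain of nested pairs in which consecutive
# pairs are stacked or separated by at most `max_gap` unpaired/bulged
# positions on either side, with at most `max_defects` such interruptions
# in the whole stem (a helix with a few small interior loops). An
# unrestricted nested chain is not a stem: maximum-weight structures of
# random sequences contain long cascades of pairs scattered across many
# short bulge-separated helices, which would pass a chain-length
# threshold. A mature/star duplex built from a reverse complement with a
# couple of interior mismatches has at most that many interruptions, so it
# remains one stem, while random cascades (roughly one interruption every
# two to three pairs) fragment. Both bounds were calibrated on planted
# versus dinucleotide-shuffled precursors.
longest_stem <- function(pairs, max_gap = 2L, max_defects = 2L) {
  o <- order(pairs[, 1L])
  p <- pairs[o, , drop = FALSE]
  m <- nrow(p)
  if (m == 0L) return(p)
  nd <- max_defects + 1L
  # len[k, d]: longest chain ending at pair k having used d-1 defects
  len <- matrix(1L, m, nd)
  prev <- matrix(NA_integer_, m, nd)      # predecessor pair index
  prevd <- matrix(NA_integer_, m, nd)     # predecessor defect column
  for (k in seq_len(m)) {
    for (q in seq_len(k - 1L)) {
      di <- p[k, 1L] - p[q, 1L]
      dj <- p[q, 2L] - p[k, 2L]
      if (di < 1L || dj < 1L || di > max_gap + 1L || dj > max_gap + 1L)
        next
      step <- if (di > 1L || dj > 1L) 1L else 0L
      for (d in seq_len(nd)) {
        d2 <- d + step
        if (d2 > nd) next
        if (len[q, d] + 1L > len[k, d2]) {
          len[k, d2] <- len[q, d] + 1L
          prev[k, d2] <- q
          prevd[k, d2] <- d
        }
      }
    }
  }
  best <- which(len == max(len), arr.ind = TRUE)[1L, ]
  k <- best[[1L]]; d <- best[[2L]]
  chain <- integer(0)
  while (!is.na(k)) {
    chain <- c(k, chain)
    k2 <- prev[k, d]; d <- prevd[k, d]; k <- k2
  }
  p[chain, , drop = FALSE]
}

#' Decide whether hairpin features describe an acceptable pre-miRNA
#'
#' A candidate precursor window is accepted when its longest stem carries at
#' least `min_stem_pairs` base pairs, at least `min_paired_fraction` of the
#' mature-arm bases are paired, the mature sequence lies on one arm rather
#' than spanning the hairpin loop, and the loop is at least `min_loop_length`
#' nucleotides. All thresholds are configurable; the defaults were calibrated
#' on planted hairpins versus dinucleotide-shuffled negatives.
#'
#' @param features An `mf_hairpin_features` object.
#' @param min_stem_pairs Minimum base pairs in the longest stem (default 14).
#' @param min_paired_fraction Minimum paired fraction of mature bases
#'   (default 0.6).
#' @param min_loop_length Minimum hairpin loop length in nt (default 3).
#'
#' @return List with `valid` (logical) and `reasons` (character vector of
#'   failed criteria, empty when valid).
#' @export
is_valid_hairpin <- function(features, min_stem_pairs = 14L,
                             min_paired_fraction = 0.6,
                             min_loop_length = 3L) {
  stopifnot(inherits(features, "mf_hairpin_features"))
  reasons <- character(0)
  if (features$stem_pairs < min_stem_pairs)
    reasons <- c(reasons, "stem_pairs")
  if (features$paired_fraction_of_mature < min_paired_fraction)
    reasons <- c(reasons, "paired_fraction")
  if (features$arm == "loop_spanning")
    reasons <- c(reasons, "arm")
  if (is.na(features$loop_length) || features$loop_length < min_loop_length)
    reasons <- c(reasons, "loop_length")
  list(valid = length(reasons) == 0L, reasons = reasons)
}
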