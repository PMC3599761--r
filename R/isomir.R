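# isomiR family grouping and representative selection. A family collects
# sequence variants of a reference mature miRNA that differ by terminal
# 5'/3' length offsets (bounded) and/or at most one substitution; the most
# abundant member represents the family and its count is the family's
# reported count.

# Best ungapped alignment of a tag against a reference allowing terminal
# offsets up to max_offset: returns NULL when the tag is not an acceptable
# variant, else a difference score (mismatches + |d5| + |d3|).
isomir_distance <- function(tag, ref, max_offset = 3L, max_subst = 1L) {
  lt <- nchar(tag); lr <- nchar(ref)
  best <- NULL
  for (d5 in seq.int(-max_offset, max_offset)) {
    d3 <- (d5 + lt) - lr
    if (abs(d3) > max_offset) next
    # overlap region in reference coordinates
    os <- max(0L, d5); oe <- min(lr, d5 + lt)
    if (oe <= os) next
    ref_part <- substr(ref, os + 1L, oe)
    tag_part <- substr(tag, os - d5 + 1L, oe - d5)
    mism <- sum(utf8ToInt(ref_part) != utf8ToInt(tag_part))
    if (mism > max_subst) next
    score <- mism + abs(d5) + abs(d3)
    if (is.null(best) || score < best) best <- score
  }
  best
}

#' Group tags into isomiR families around reference sequences
#'
#' A tag joins a reference's family when it can be aligned to the
#' reference with 5'/3' terminal offsets of at most `max_offset`
#' nucleotides and at most `max_subst` substitutions over the aligned
#' region. Each tag joins at most one family: the reference with the
#' fewest differences wins, ties going to the more abundant reference.
#'
#' @param tags Tag data.frame (columns `sequence` plus per-library
#'   counts).
#' @param references Named character vector of reference mature sequences
#'   (names become family ids).
#' @param max_offset Maximum terminal offset per end in nt (default 3).
#' @param max_subst Maximum substitutions (default 1).
#'
#' @return List of class `mf_isomir_families`: `families` (list, one per
#'   reference with members data.frame, representative, and per-library
#'   representative/total counts) and `unassigned` (tags joining no
#'   family).
#' @export
group_isomirs <- function(tags, references, max_offset = 3L, max_subst = 1L) {
  cc <- count_cols(tags)
  ref_ids <- names(references)
  stopifnot(!is.null(ref_ids), all(nzchar(ref_ids)))
  ref_counts <- vapply(ref_ids, function(id) {
    i <- match(references[[id]], tags$sequence)
    if (is.na(i)) 0 else sum(as.numeric(tags[i, cc]))
  }, numeric(1))

  assignment <- rep(NA_character_, nrow(tags))
  for (r in seq_len(nrow(tags))) {
    scores <- vapply(ref_ids, function(id) {
      d <- isomir_distance(tags$sequence[r], references[[id]],
                           max_offset, max_subst)
      if (is.null(d)) Inf else d
    }, numeric(1))
    if (all(is.infinite(scores))) next
    best <- which(scores == min(scores))
    if (length(best) > 1L) best <- best[which.max(ref_counts[best])]
    assignment[r] <- ref_ids[best]
  }

  families <- lapply(ref_ids, function(id) {
    mem <- tags[!is.na(assignment) & assignment == id, , drop = FALSE]
    fam <- list(id = id, reference = references[[id]], members = mem)
    class(fam) <- "mf_isomir_family"
    if (nrow(mem)) {
      rep_tag <- select_representative(fam)
      fam$representative <- rep_tag
      ri <- match(rep_tag, mem$sequence)
      fam$representative_count <- setNames(as.numeric(mem[ri, cc]),
                                           sub("^count_", "", cc))
      fam$total_count <- setNames(vapply(cc, function(c) sum(mem[[c]]),
                                         numeric(1)),
                                  sub("^count_", "", cc))
    } else {
      fam$representative <- NA_character_
      fam$representative_count <- setNames(rep(0, length(cc)),
                                           sub("^count_", "", cc))
      fam$total_count <- fam$representative_count
    }
    fam
  })
  names(families) <- ref_ids
  out <- list(families = families,
              unassigned = tags[is.na(assignment), , drop = FALSE])
  class(out) <- "mf_isomir_families"
  out
}

#' Select the representative sequence of an isomiR family
#'
#' The most abundant member (highest summed count across libraries)
#' represents the family; ties are broken in favor of the longer sequence,
#' then lexicographic order.
#'
#' @param family An `mf_isomir_family` (list with a `members` tag
#'   data.frame).
#' @return The representative tag sequence.
#' @export
select_representative <- function(family) {
  mem <- family$members
  if (is.null(mem) || nrow(mem) == 0L) stop("empty isomiR family")
  cc <- count_cols(mem)
  tot <- rowSums(mem[, cc, drop = FALSE])
  ord <- order(-tot, -nchar(mem$sequence), mem$sequence)
  mem$sequence[ord[1L]]
}

#' Correlation between family representative and total counts
#'
#' Pearson correlation, per library, between the log10(count + 1) of each
#' family's most abundant member and the log10(total + 1) of all its
#' members, quantifying how faithfully the representative tracks the
#' family's overall abundance.
#'
#' @param families An `mf_isomir_families` object (or its `families`
#'   list). Families with no members are dropped.
#' @return Named numeric of Pearson r per library.
#' @export
representative_total_correlation <- function(families) {
  fams <- if (inherits(families, "mf_isomir_families")) families$families
          else families
  fams <- Filter(function(f) sum(f$total_count) > 0, fams)
  if (length(fams) < 3L)
    stop("need at least 3 families with nonzero counts")
  libs <- names(fams[[1L]]$total_count)
  vapply(libs, function(lib) {
    rep_c <- vapply(fams, function(f) f$representative_count[[lib]],
                    numeric(1))
    tot_c <- vapply(fams, function(f) f$total_count[[lib]], numeric(1))
    cor(log10(rep_c + 1), log10(tot_c + 1))
  }, numeric(1))
}
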