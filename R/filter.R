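# Read filtering and collapsing. Unique tags ("sequ-seqs") are represented
# as a data.frame with a `sequence` column, a `length` column, and one or
# more count columns named count_<library>. The filter cascade is: adapter
# trim -> size filter (10-40 nt) -> N filter -> low-complexity filter ->
# minimum-count filter; every step is configurable and can be disabled.

#' Trim a 3' sequencing adapter from reads
#'
#' Removes the longest read suffix that exactly matches a prefix of the
#' adapter, requiring at least `min_overlap` matching bases. When the full
#' adapter occurs internally more than once, trimming happens at the
#' leftmost occurrence. Reads in which no adapter is found are returned
#' unchanged and flagged.
#'
#' @param reads Character vector of read sequences.
#' @param adapter Adapter sequence (non-empty).
#' @param min_overlap Minimum read/adapter overlap in nt (default 8).
#'
#' @return List with `trimmed` (character vector) and `no_adapter`
#'   (logical vector, TRUE where no adapter overlap was found).
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 8L) {
  stopifnot(nchar(adapter) > 0L)
  adapter <- to_dna(adapter)
  reads <- to_dna(reads)
  min_overlap <- min(as.integer(min_overlap), nchar(adapter))
  trimmed <- reads
  found <- logical(length(reads))
  for (r in seq_along(reads)) {
    read <- reads[[r]]
    n <- nchar(read)
    for (i in seq_len(max(0L, n - min_overlap + 1L))) {
      len <- min(nchar(adapter), n - i + 1L)
      if (substr(read, i, i + len - 1L) == substr(adapter, 1L, len)) {
        trimmed[[r]] <- substr(read, 1L, i - 1L)
        found[[r]] <- TRUE
        break
      }
    }
  }
  list(trimmed = trimmed, no_adapter = !found)
}

#' Collapse reads to unique tags with counts
#'
#' @param reads Character vector of (trimmed) read sequences.
#' @param library_id Library label; the count column is named
#'   `count_<library_id>`.
#'
#' @return Tag data.frame with columns `sequence`, `length`,
#'   `count_<library_id>`, sorted by decreasing count then sequence.
#' @export
collapse_reads <- function(reads, library_id = "A") {
  reads <- to_dna(reads)
  if (length(reads) == 0L) {
    out <- data.frame(sequence = character(0), length = integer(0),
                      count = integer(0))
    names(out)[3L] <- paste0("count_", library_id)
    return(out)
  }
  tab <- table(reads)
  out <- data.frame(sequence = names(tab), length = nchar(names(tab)),
                    count = as.integer(tab), stringsAsFactors = FALSE)
  names(out)[3L] <- paste0("count_", library_id)
  out <- out[order(-out[[3L]], out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge per-library tag tables into one table with per-library counts
#'
#' @param tag_tables Named list of tag tables from [collapse_reads()].
#' @return Tag data.frame with `sequence`, `length`, and one count column
#'   per library (absent tags get count 0).
#' @export
merge_tag_tables <- function(tag_tables) {
  stopifnot(length(tag_tables) >= 1L)
  seqs <- sort(unique(unlist(lapply(tag_tables, `[[`, "sequence"))))
  out <- data.frame(sequence = seqs, length = nchar(seqs),
                    stringsAsFactors = FALSE)
  for (lib in names(tag_tables)) {
    tt <- tag_tables[[lib]]
    cc <- grep("^count_", names(tt), value = TRUE)
    idx <- match(seqs, tt$sequence)
    cnt <- ifelse(is.na(idx), 0L, tt[[cc]][idx])
    out[[paste0("count_", lib)]] <- as.integer(cnt)
  }
  tot <- rowSums(out[, grep("^count_", names(out)), drop = FALSE])
  out <- out[order(-tot, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

count_cols <- function(tags) grep("^count_", names(tags), value = TRUE)

tag_read_totals <- function(tags) {
  cc <- count_cols(tags)
  out <- vapply(cc, function(c) sum(tags[[c]]), numeric(1))
  names(out) <- sub("^count_", "", cc)
  out
}

#' Filter tags by length
#'
#' In-silico analog of gel size selection: keeps tags whose length lies in
#' the inclusive range `[min_len, max_len]` (default 10-40 nt).
#'
#' @param tags Tag data.frame.
#' @param min_len,max_len Inclusive length bounds in nt.
#' @return List with `kept` and `removed` tag data.frames.
#' @export
size_filter <- function(tags, min_len = 10L, max_len = 40L) {
  keep <- tags$length >= min_len & tags$length <= max_len
  list(kept = tags[keep, , drop = FALSE],
       removed = tags[!keep, , drop = FALSE])
}

#' Apply sequence-quality filters to collapsed tags
#'
#' Removes tags containing N, low-complexity tags in which a single base
#' accounts for at least `homopolymer_fraction` of the sequence, and tags
#' whose total count across libraries is below `min_count` (singleton
#' removal by default). Each step is recorded in an ordered filter report.
#'
#' @param tags Tag data.frame.
#' @param min_count Minimum total count across libraries (default 2; set to
#'   0 or 1 to disable).
#' @param homopolymer_fraction Single-base content at or above which a tag
#'   is treated as low-complexity (default 0.9; set > 1 to disable).
#' @return List with `tags` (mappable tags) and `report` (a filter-report
#'   data.frame, see [filter_report()]).
#' @export
quality_filters <- function(tags, min_count = 2L,
                            homopolymer_fraction = 0.9) {
  steps <- list()
  has_n <- grepl("N", tags$sequence, fixed = TRUE)
  steps$n_filter <- tag_read_totals(tags[has_n, , drop = FALSE])
  tags <- tags[!has_n, , drop = FALSE]

  frac <- max_base_fraction(tags$sequence)
  low <- frac >= homopolymer_fraction
  steps$low_complexity <- tag_read_totals(tags[low, , drop = FALSE])
  tags <- tags[!low, , drop = FALSE]

  tot <- rowSums(tags[, count_cols(tags), drop = FALSE])
  rare <- tot < min_count
  steps$min_count <- tag_read_totals(tags[rare, , drop = FALSE])
  tags <- tags[!rare, , drop = FALSE]

  list(tags = tags, removed_per_step = steps)
}

max_base_fraction <- function(seqs) {
  if (length(seqs) == 0L) return(numeric(0))
  counts <- vapply(c("A", "C", "G", "T"), function(b) {
    nchar(seqs) - nchar(gsub(b, "", seqs, fixed = TRUE))
  }, numeric(length(seqs)))
  counts <- matrix(counts, nrow = length(seqs))
  apply(counts, 1L, max) / nchar(seqs)
}

#' Run the full filter cascade on per-library reads
#'
#' Applies, in order: optional 3' adapter trimming, collapsing to unique
#' tags, size selection, N removal, low-complexity removal, and the
#' minimum-count filter. Read counts are conserved at every stage:
#' `reads_in = reads_out + reads_removed`, and `reads_out` of one filter is
#' `reads_in` of the next.
#'
#' @param reads_by_library Named list of character vectors of read
#'   sequences (one element per library).
#' @param adapter Optional adapter sequence; `NULL` skips trimming.
#' @param min_overlap Minimum adapter overlap for trimming.
#' @param min_len,max_len Size-selection bounds (nt).
#' @param min_count Minimum total tag count.
#' @param homopolymer_fraction Low-complexity threshold.
#'
#' @return List with `tags` (mappable tag table with per-library counts),
#'   `report` (filter-report data.frame with columns `filter`, `library`,
#'   `reads_in`, `reads_out`, `reads_removed`), and `mappable_totals`
#'   (named numeric, reads per library surviving the cascade).
#' @export
filter_cascade <- function(reads_by_library, adapter = NULL,
                           min_overlap = 8L, min_len = 10L, max_len = 40L,
                           min_count = 2L, homopolymer_fraction = 0.9) {
  libs <- names(reads_by_library)
  stopifnot(!is.null(libs), all(nzchar(libs)))

  if (!is.null(adapter)) {
    reads_by_library <- lapply(reads_by_library, function(r) {
      trim_adapter(r, adapter, min_overlap)$trimmed
    })
  }
  input_totals <- vapply(reads_by_library, length, numeric(1))

  tag_tables <- lapply(libs, function(lib) {
    collapse_reads(reads_by_library[[lib]], lib)
  })
  names(tag_tables) <- libs
  tags <- merge_tag_tables(tag_tables)

  sz <- size_filter(tags, min_len, max_len)
  removed <- list(size_filter = tag_read_totals(sz$removed))
  qf <- quality_filters(sz$kept, min_count, homopolymer_fraction)
  removed <- c(removed, qf$removed_per_step)

  report <- filter_report(input_totals, removed)
  list(tags = qf$tags, report = report,
       mappable_totals = tag_read_totals(qf$tags))
}

#' Build an ordered filter report from per-step removal totals
#'
#' @param input_totals Named numeric of input read counts per library.
#' @param removed_per_step Ordered named list; each element a named numeric
#'   of reads removed per library by that filter.
#' @return Data.frame with columns `filter`, `library`, `reads_in`,
#'   `reads_out`, `reads_removed`.
#' @export
filter_report <- function(input_totals, removed_per_step) {
  libs <- names(input_totals)
  rows <- list()
  current <- input_totals
  for (step in names(removed_per_step)) {
    rem <- removed_per_step[[step]][libs]
    rem[is.na(rem)] <- 0
    rows[[step]] <- data.frame(filter = step, library = libs,
                               reads_in = as.numeric(current),
                               reads_out = as.numeric(current - rem),
                               reads_removed = as.numeric(rem),
                               stringsAsFactors = FALSE)
    current <- current - rem
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Length distribution of mappable tags
#'
#' Counts are weighted by tag read counts (not distinct sequences), per
#' library; fractions within each library sum to 1.
#'
#' @param tags Mappable tag data.frame.
#' @return Data.frame with columns `length`, `library`, `count`,
#'   `fraction`, sorted by library then length.
#' @export
length_histogram <- function(tags) {
  cc <- count_cols(tags)
  rows <- lapply(cc, function(col) {
    lib <- sub("^count_", "", col)
    agg <- tapply(tags[[col]], tags$length, sum)
    cnt <- as.numeric(agg)
    data.frame(length = as.integer(names(agg)), library = lib,
               count = cnt, fraction = cnt / sum(cnt),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$library, out$length), , drop = FALSE]
  rownames(out) <- NULL
  out
}
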