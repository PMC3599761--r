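# Independent reference implementations used to validate the package's
# optimized code paths. These are deliberately naive (quadratic scans,
# direct arithmetic) so that agreement is meaningful.

# Random DNA string helper for tests.
rand_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

rc <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Naive tag-to-target alignment: slide every tag over every position of
# every target (both strands when requested) and count mismatches
# directly. Same output contract as map_tags().
naive_map <- function(tags, targets, max_mismatch = 1L,
                      both_strands = FALSE) {
  seqs <- unique(toupper(tags))
  seqs <- seqs[!grepl("N", seqs, fixed = TRUE)]
  strands <- if (both_strands) c("+", "-") else "+"
  rows <- list()
  for (tag in seqs) {
    for (s in strands) {
      q <- if (s == "+") tag else rc(tag)
      qc <- strsplit(q, "")[[1L]]
      L <- length(qc)
      for (tn in names(targets)) {
        tc <- strsplit(toupper(targets[[tn]]), "")[[1L]]
        if (length(tc) < L) next
        for (st in seq_len(length(tc) - L + 1L)) {
          mm <- sum(qc != tc[st:(st + L - 1L)])
          if (mm <= max_mismatch) {
            rows[[length(rows) + 1L]] <- data.frame(
              tag = tag, target = tn, start = st - 1L, end = st - 1L + L,
              strand = s, mismatches = as.integer(mm),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(tag = character(0), target = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$tag, out$target, out$start, out$strand), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
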