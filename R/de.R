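# Two-library differential expression for unreplicated count data:
# counts-per-million normalization against mappable totals, an exact
# two-sided Fisher test per miRNA (the proportional-count test used for
# unreplicated deep-sequencing libraries), direction/specificity calls,
# and abundance-share summaries. P-value thresholds are applied raw (no
# multiple-testing correction by default, matching the single worked
# criterion P < 0.001 with > 1.5-fold change); a Benjamini-Hochberg option
# is available.

#' Normalize a count to reads per million mappable sequences
#'
#' @param count Numeric vector of raw counts.
#' @param library_total Total mappable reads in the library (positive).
#' @return `count / library_total * 1e6`.
#' @export
normalize_cpm <- function(count, library_total) {
  if (any(library_total <= 0)) stop("library_total must be positive")
  count / library_total * 1e6
}

#' Two-sided Fisher's exact test for a 2x2 count table
#'
#' Exact two-sided p-value for the table
#' `[[count_A, N_A - count_A], [count_B, N_B - count_B]]`, computed by the
#' point-probability rule: the sum of hypergeometric probabilities of all
#' outcomes no more likely than the observed one (likelihood comparison at
#' relative tolerance 1e-7). Vectorized over counts.
#'
#' @param count_A,count_B Per-library counts (non-negative, at most the
#'   library totals).
#' @param N_A,N_B Library totals (mappable reads).
#' @return Two-sided p-value(s) in `[0, 1]`.
#' @export
fisher_test <- function(count_A, count_B, N_A, N_B) {
  if (any(c(count_A, count_B, N_A, N_B) < 0))
    stop("counts and totals must be non-negative")
  if (any(count_A > N_A) || any(count_B > N_B))
    stop("counts cannot exceed library totals")
  n <- max(length(count_A), length(count_B))
  count_A <- rep_len(count_A, n); count_B <- rep_len(count_B, n)
  N_A <- rep_len(N_A, n); N_B <- rep_len(N_B, n)
  vapply(seq_len(n), function(i) {
    fisher_p_one(count_A[i], count_B[i], N_A[i], N_B[i])
  }, numeric(1))
}

fisher_p_one <- function(a, b, NA_, NB_) {
  k <- a + b
  if (k == 0 || k == NA_ + NB_) return(1)
  lo <- max(0, k - NB_); hi <- min(k, NA_)
  x <- lo:hi
  dens <- dhyper(x, NA_, NB_, k)
  p_obs <- dens[a - lo + 1L]
  p <- sum(dens[dens <= p_obs * (1 + 1e-7)])
  min(1, p)
}

#' Build per-miRNA expression records for two libraries
#'
#' @param ids miRNA identifiers.
#' @param count_A,count_B Raw counts per library.
#' @param N_A,N_B Mappable library totals.
#' @param pseudocount Added to both normalized counts before fold change
#'   when either raw count is zero (default 0: zero-count miRNAs get an
#'   undefined fold change and are handled by the specificity classes).
#'
#' @return Data.frame with ids, raw counts, CPM values, fold change
#'   (B over A), log2 fold change, and Fisher p-value.
#' @export
expression_records <- function(ids, count_A, count_B, N_A, N_B,
                               pseudocount = 0) {
  cpm_A <- normalize_cpm(count_A, N_A)
  cpm_B <- normalize_cpm(count_B, N_B)
  fa <- cpm_A; fb <- cpm_B
  if (pseudocount > 0) {
    zero <- count_A == 0 | count_B == 0
    fa[zero] <- fa[zero] + normalize_cpm(pseudocount, N_A)
    fb[zero] <- fb[zero] + normalize_cpm(pseudocount, N_B)
  }
  fold <- ifelse(fa > 0 & fb > 0, fb / fa, NA_real_)
  data.frame(id = ids, count_A = count_A, count_B = count_B,
             N_A = N_A, N_B = N_B, cpm_A = cpm_A, cpm_B = cpm_B,
             fold_change = fold, log2_fold_change = log2(fold),
             p_value = fisher_test(count_A, count_B, N_A, N_B),
             stringsAsFactors = FALSE)
}

#' Classify library specificity of each miRNA
#'
#' A miRNA is A-specific when it is detected in library A (count at or
#' above `presence_threshold`) and absent from B (count below the
#' threshold), and symmetrically; otherwise co-expressed when present in
#' both.
#'
#' @param records Expression-record data.frame.
#' @param presence_threshold Minimum count regarded as detected
#'   (default 1).
#' @return `records` with a `specificity` column (`A_specific`,
#'   `B_specific`, `co_expressed`).
#' @export
classify_specificity <- function(records, presence_threshold = 1) {
  a <- records$count_A; b <- records$count_B
  records$specificity <- ifelse(
    a >= presence_threshold & b < presence_threshold, "A_specific",
    ifelse(b >= presence_threshold & a < presence_threshold, "B_specific",
           "co_expressed"))
  records
}

#' Call differentially expressed miRNAs
#'
#' Among co-expressed miRNAs, a miRNA is differentially expressed when its
#' Fisher p-value is strictly below `p_threshold`. Direction is `up`
#' (higher in B) when the normalized fold change exceeds `fc_threshold`,
#' `down` when it is below `1 / fc_threshold`; DE miRNAs inside the
#' fold-change band keep their call with direction from the sign of the
#' log2 fold change.
#'
#' @param records Expression records with specificity classified (records
#'   lacking a `specificity` column are first classified with defaults).
#' @param p_threshold P-value threshold (default 0.001, strict
#'   inequality).
#' @param fc_threshold Fold-change threshold (default 1.5).
#' @param adjust Apply Benjamini-Hochberg correction before thresholding
#'   (default FALSE; raw p-values as in unreplicated two-library designs).
#' @return `records` with `is_DE`, `direction`, and (when `adjust`)
#'   `p_adjusted` columns.
#' @export
call_de <- function(records, p_threshold = 0.001, fc_threshold = 1.5,
                    adjust = FALSE) {
  if (is.null(records$specificity)) records <- classify_specificity(records)
  p <- records$p_value
  if (adjust) {
    records$p_adjusted <- stats::p.adjust(p, method = "BH")
    p <- records$p_adjusted
  }
  co <- records$specificity == "co_expressed"
  records$is_DE <- co & p < p_threshold
  dir <- rep("none", nrow(records))
  fold <- records$fold_change
  dir[records$is_DE & !is.na(fold) & fold > fc_threshold] <- "up"
  dir[records$is_DE & !is.na(fold) & fold < 1 / fc_threshold] <- "down"
  mid <- records$is_DE & dir == "none" & !is.na(fold)
  dir[mid] <- ifelse(fold[mid] > 1, "up", "down")
  records$direction <- dir
  records
}

#' Share of total miRNA counts captured by the top-n miRNAs
#'
#' Per library, ranks miRNAs by count and reports the fraction of total
#' miRNA counts contributed by the `n` most abundant ones.
#'
#' @param records Expression records.
#' @param n Number of top miRNAs (default 10).
#' @return List with `share` (named numeric per library) and `ranked`
#'   (data.frame of the per-library top-n ids and counts).
#' @export
abundance_summary <- function(records, n = 10L) {
  if (nrow(records) < n) {
    warning("fewer records than n; share computed over all records")
    n <- nrow(records)
  }
  share <- c(A = NA_real_, B = NA_real_)
  ranked <- list()
  for (lib in c("A", "B")) {
    cnt <- records[[paste0("count_", lib)]]
    ord <- order(-cnt, records$id)
    top <- ord[seq_len(n)]
    share[[lib]] <- sum(cnt[top]) / sum(cnt)
    ranked[[lib]] <- data.frame(library = lib, rank = seq_len(n),
                                id = records$id[top], count = cnt[top],
                                stringsAsFactors = FALSE)
  }
  list(share = share, ranked = do.call(rbind, ranked))
}

#' Co-expression summary
#'
#' @param records Expression records with specificity classified.
#' @return List with `n_total`, `n_coexpressed`, and `percent`
#'   (co-expressed percentage, rounded to 2 decimals).
#' @export
coexpression_summary <- function(records) {
  if (nrow(records) == 0L) stop("no records")
  if (is.null(records$specificity)) records <- classify_specificity(records)
  n_co <- sum(records$specificity == "co_expressed")
  list(n_total = nrow(records), n_coexpressed = n_co,
       percent = round(n_co / nrow(records) * 100, 2))
}
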