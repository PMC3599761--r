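# Microarray-style validation utilities: probe-to-miRNA median collapse,
# quantile normalization of log2 intensities, and Pearson correlation for
# replicate agreement and cross-platform concordance.

#' Collapse probe-level intensities to miRNAs by the median
#'
#' Each miRNA's row is the per-sample median over its probes; probes not
#' present in the map are dropped and counted.
#'
#' @param probe_matrix Numeric matrix, rows = probes (rownames are probe
#'   ids), columns = samples.
#' @param probe_to_mirna Named character vector mapping probe id to miRNA
#'   id (each probe maps to at most one miRNA).
#'
#' @return List with `matrix` (miRNA-level matrix) and `n_unmapped`
#'   (number of probes dropped).
#' @export
collapse_probes_median <- function(probe_matrix, probe_to_mirna) {
  if (length(probe_to_mirna) == 0L) stop("empty probe-to-miRNA map")
  probes <- rownames(probe_matrix)
  mirna <- probe_to_mirna[probes]
  unmapped <- is.na(mirna)
  keep <- probe_matrix[!unmapped, , drop = FALSE]
  mirna <- mirna[!unmapped]
  ids <- sort(unique(mirna))
  out <- t(vapply(ids, function(id) {
    apply(keep[mirna == id, , drop = FALSE], 2L, median)
  }, numeric(ncol(probe_matrix))))
  colnames(out) <- colnames(probe_matrix)
  list(matrix = out, n_unmapped = sum(unmapped))
}

#' Quantile-normalize an intensity matrix
#'
#' Forces every column to share the same empirical distribution: each
#' value is replaced by the cross-column mean of the values at its rank,
#' with ties within a column receiving the mean of their rank values.
#'
#' @param matrix Numeric matrix with at least 2 columns and finite values.
#' @return The normalized matrix.
#' @export
quantile_normalize <- function(matrix) {
  if (ncol(matrix) < 2L) stop("need at least 2 columns")
  if (!all(is.finite(matrix))) stop("non-finite values in matrix")
  limma::normalizeQuantiles(matrix, ties = TRUE)
}

#' Scale columns to a common 75th percentile
#'
#' Alternative normalization that divides each column by its upper
#' quartile and rescales to the mean upper quartile, for users who prefer
#' quartile scaling over full quantile normalization.
#'
#' @param matrix Numeric matrix.
#' @return The scaled matrix.
#' @export
upper_quartile_scale <- function(matrix) {
  uq <- apply(matrix, 2L, quantile, probs = 0.75)
  if (any(uq <= 0)) stop("non-positive upper quartiles")
  sweep(matrix, 2L, uq / mean(uq), "/")
}

#' Pearson correlation with significance
#'
#' Standard product-moment correlation; the p-value comes from the t
#' transform with n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (at least 3), each with
#'   nonzero variance.
#' @return List of class `mf_correlation` with `r`, `n`, `p`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance")
  r <- cor(x, y)
  tval <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(-abs(tval), df = n - 2)
  out <- list(r = r, n = n, p = p)
  class(out) <- "mf_correlation"
  out
}

#' @export
print.mf_correlation <- function(x, ...) {
  cat(sprintf("Pearson r = %.4f (n = %d, p = %.3g)\n", x$r, x$n, x$p))
  invisible(x)
}

#' Pairwise replicate correlation matrix
#'
#' @param matrix Numeric matrix with samples in columns.
#' @return List with `r` (correlation matrix) and `mean_r` (mean of the
#'   off-diagonal correlations).
#' @export
replicate_correlation <- function(matrix) {
  r <- cor(matrix)
  off <- r[upper.tri(r)]
  list(r = r, mean_r = mean(off))
}

#' Cross-platform concordance of fold changes
#'
#' Pearson correlation of log2 fold changes between sequencing and
#' microarray over the miRNAs detected by both platforms.
#'
#' @param seq_fold_changes,array_fold_changes Named numeric vectors of
#'   log2 fold changes keyed by miRNA id.
#' @return An `mf_correlation` over the identifier intersection (size in
#'   `n`).
#' @export
cross_platform_concordance <- function(seq_fold_changes,
                                       array_fold_changes) {
  shared <- intersect(names(seq_fold_changes), names(array_fold_changes))
  if (length(shared) < 3L) stop("fewer than 3 shared miRNA identifiers")
  pearson(seq_fold_changes[shared], array_fold_changes[shared])
}

#' Simulate a probe-level microarray from expression values
#'
#' Emulates the validation experiment: each miRNA gets `n_probes` probes
#' with probe-specific offsets; each tissue is measured in `n_replicates`
#' biological replicates whose log2 intensities are the underlying log2
#' expression plus replicate noise and measurement noise.
#'
#' @param log2_expression Numeric matrix, rows = miRNAs (named), columns =
#'   tissues, of underlying log2 expression values.
#' @param n_probes Probes per miRNA (default 3).
#' @param n_replicates Biological replicates per tissue (default 3).
#' @param probe_sd SD of fixed probe affinity offsets (default 0.5).
#' @param replicate_sd SD of per-replicate biological noise (default 0.3).
#' @param noise_sd SD of per-measurement noise (default 0.2).
#' @param seed Integer seed.
#'
#' @return List with `probe_matrix` (probes x (tissue.replicate) log2
#'   intensities) and `probe_to_mirna` (named character map).
#' @export
simulate_probe_matrix <- function(log2_expression, n_probes = 3L,
                                  n_replicates = 3L, probe_sd = 0.5,
                                  replicate_sd = 0.3, noise_sd = 0.2,
                                  seed = 1L) {
  set.seed(seed)
  ids <- rownames(log2_expression)
  tissues <- colnames(log2_expression)
  probes <- paste0(rep(ids, each = n_probes), "_p",
                   rep(seq_len(n_probes), length(ids)))
  probe_off <- rnorm(length(probes), 0, probe_sd)
  cols <- as.vector(outer(seq_len(n_replicates), tissues,
                          function(r, t) paste0(t, ".rep", r)))
  mat <- matrix(NA_real_, length(probes), length(cols),
                dimnames = list(probes, cols))
  for (t in seq_along(tissues)) {
    rep_off <- matrix(rnorm(length(ids) * n_replicates, 0, replicate_sd),
                      length(ids), n_replicates)
    for (r in seq_len(n_replicates)) {
      col <- paste0(tissues[t], ".rep", r)
      base <- log2_expression[, t] + rep_off[, r]
      mat[, col] <- rep(base, each = n_probes) + probe_off +
        rnorm(length(probes), 0, noise_sd)
    }
  }
  map <- rep(ids, each = n_probes)
  names(map) <- probes
  list(probe_matrix = mat, probe_to_mirna = map)
}
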