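# End-to-end orchestration: filter cascade -> other-RNA removal -> tier
# annotation -> isomiR collapsing -> differential expression -> summary
# tables, from a single configuration with every stage parameter explicit.

#' Build and validate a pipeline configuration
#'
#' Inputs may be given in memory (named list of read vectors, named
#' character sequence vectors, data.frames) or as file paths (FASTQ for
#' reads, FASTA for genome/catalogs); file inputs are loaded lazily by
#' [run_pipeline()]. All stage parameters are recorded here so that every
#' assumed default is visible and serializable.
#'
#' @param reads Named list of read character vectors (two libraries), or
#'   NULL when `fastq` paths are given.
#' @param fastq Named list/vector of FASTQ paths, one per library.
#' @param genome Named character of contigs, or a FASTA path, or NULL
#'   (candidate calling skipped).
#' @param known_precursors,mammal_precursors Named character catalogs or
#'   FASTA paths.
#' @param other_rna Data.frame (`name`, `class`, `sequence`), a FASTA path
#'   whose headers are `class-name`, or NULL.
#' @param adapter Optional 3' adapter to trim.
#' @param min_overlap Minimum adapter overlap (nt).
#' @param min_len,max_len Size-selection bounds (nt).
#' @param min_count Minimum total tag count.
#' @param homopolymer_fraction Low-complexity threshold.
#' @param max_mismatch Mapping mismatch allowance.
#' @param flank Candidate window flank (nt).
#' @param min_candidate_len Tags must be longer than this for candidate
#'   calling.
#' @param slop Mature-locus clustering slop (nt).
#' @param hairpin_thresholds List for [is_valid_hairpin()].
#' @param fold_weights Pairing weights for [fold()].
#' @param max_offset,max_subst isomiR family bounds.
#' @param p_threshold,fc_threshold,presence_threshold DE parameters.
#' @param top_n Top-n for the abundance share summary.
#' @param seed Integer seed recorded in the manifest.
#' @param outdir Optional output directory for TSV tables and manifest.
#'
#' @return A list of class `mf_pipeline_config`.
#' @export
pipeline_config <- function(reads = NULL, fastq = NULL, genome = NULL,
                            known_precursors = NULL,
                            mammal_precursors = NULL, other_rna = NULL,
                            adapter = NULL, min_overlap = 8L,
                            min_len = 10L, max_len = 40L, min_count = 2L,
                            homopolymer_fraction = 0.9, max_mismatch = 1L,
                            flank = 60L, min_candidate_len = 18L,
                            slop = 3L,
                            hairpin_thresholds = default_hairpin_thresholds(),
                            fold_weights = c(GC = 3, AU = 2, GU = 1),
                            max_offset = 3L, max_subst = 1L,
                            p_threshold = 0.001, fc_threshold = 1.5,
                            presence_threshold = 1, top_n = 10L,
                            seed = 1L, outdir = NULL) {
  if (is.null(reads) && is.null(fastq))
    stop("supply reads (in memory) or fastq (paths)")
  for (p in unlist(fastq)) {
    if (!file.exists(p)) stop("input file not found: ", p)
  }
  if (p_threshold <= 0 || p_threshold > 1 || fc_threshold < 1)
    stop("p_threshold must be in (0, 1] and fc_threshold >= 1")
  cfg <- mget(names(formals(pipeline_config)), environment())
  class(cfg) <- "mf_pipeline_config"
  cfg
}

load_seq_input <- function(x) {
  if (is.null(x) || !is.character(x) || length(x) != 1L || !file.exists(x))
    return(x)
  read_fasta(x)
}

load_other_rna <- function(x) {
  if (is.null(x) || is.data.frame(x)) return(x)
  seqs <- read_fasta(x)
  data.frame(name = names(seqs),
             class = sub("-.*$", "", names(seqs)),
             sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Run the full small RNA discovery and profiling pipeline
#'
#' Executes, in order: the read filter cascade, other-RNA removal,
#' three-tier annotation with candidate hairpin prediction, isomiR family
#' grouping with representative selection, and Fisher-test differential
#' expression on representative counts normalized against mappable library
#' totals; then assembles the summary tables (filter report, class
#' proportions, length histogram, tier table, isomiR family table, DE
#' table, specificity/co-expression summary, top-n abundance shares). When
#' `config$outdir` is set, every table is written as TSV together with a
#' JSON run manifest.
#'
#' @param config An `mf_pipeline_config` from [pipeline_config()].
#' @return List of class `mf_pipeline_result` with elements
#'   `filter_report`, `mappable_totals`, `class_proportions`,
#'   `length_histogram`, `annotation`, `tier_table`, `isomir_table`,
#'   `isomir_families`, `de_table`, `coexpression`, `abundance_share`,
#'   `libraries`, and `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "mf_pipeline_config"))
  reads <- config$reads
  if (is.null(reads)) reads <- lapply(config$fastq, read_fastq)
  libs <- names(reads)
  stopifnot(length(libs) == 2L)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  fc <- stage("filter", filter_cascade(
    reads, adapter = config$adapter, min_overlap = config$min_overlap,
    min_len = config$min_len, max_len = config$max_len,
    min_count = config$min_count,
    homopolymer_fraction = config$homopolymer_fraction))
  mappable_totals <- fc$mappable_totals

  other_rna <- load_other_rna(config$other_rna)
  if (!is.null(other_rna) && nrow(other_rna)) {
    rr <- stage("other_rna_removal",
                remove_other_rna(fc$tags, other_rna, config$max_mismatch))
    tags <- rr$tags
    class_props <- rr$class_proportions
  } else {
    tags <- fc$tags
    class_props <- data.frame(class = character(0), library = character(0),
                              reads = numeric(0), fraction = numeric(0))
  }

  genome <- load_seq_input(config$genome)
  known <- load_seq_input(config$known_precursors)
  mammal <- load_seq_input(config$mammal_precursors)
  if (is.null(known)) known <- setNames(character(0), character(0))
  if (is.null(mammal)) mammal <- setNames(character(0), character(0))

  anno <- stage("annotation", classify_tiers(
    tags, known, mammal, genome, max_mismatch = config$max_mismatch,
    flank = config$flank, min_candidate_len = config$min_candidate_len,
    slop = config$slop, thresholds = config$hairpin_thresholds,
    weights = config$fold_weights))

  # isomiR collapsing: one family per annotation, seeded by its most
  # abundant tag.
  cc <- count_cols(tags)
  fam_rows <- list(); families <- list()
  rep_counts <- matrix(0, nrow(anno$annotations), length(cc),
                       dimnames = list(anno$annotations$name,
                                       sub("^count_", "", cc)))
  for (i in seq_len(nrow(anno$annotations))) {
    a <- anno$annotations[i, ]
    mem <- anno$members[anno$members$annotation == a$name,
                        c("sequence", cc), drop = FALSE]
    ref <- setNames(a$representative_tag, a$name)
    gi <- stage("isomir", group_isomirs(mem, ref, config$max_offset,
                                        config$max_subst))
    fam <- gi$families[[1L]]
    families[[a$name]] <- fam
    rep_counts[i, ] <- fam$representative_count
    fam_rows[[i]] <- data.frame(
      family = a$name, reference = fam$reference,
      representative = fam$representative,
      n_members = nrow(fam$members),
      n_excluded = nrow(gi$unassigned),
      t(fam$total_count), t(setNames(fam$representative_count,
                                     paste0("rep_", names(fam$representative_count)))),
      stringsAsFactors = FALSE, check.names = FALSE)
  }
  isomir_table <- if (length(fam_rows)) do.call(rbind, fam_rows) else
    data.frame(family = character(0))
  rownames(isomir_table) <- NULL

  # Differential expression on family-representative counts of mature
  # (non-star) miRNAs, against mappable library totals.
  mature <- !anno$annotations$is_star
  de_ids <- anno$annotations$name[mature]
  de <- stage("diff_expression", {
    rec <- expression_records(
      de_ids,
      count_A = rep_counts[mature, 1L],
      count_B = rep_counts[mature, 2L],
      N_A = mappable_totals[[1L]], N_B = mappable_totals[[2L]])
    rec <- classify_specificity(rec, config$presence_threshold)
    call_de(rec, config$p_threshold, config$fc_threshold)
  })
  de$tier <- anno$annotations$tier[mature]

  coexp <- if (nrow(de)) coexpression_summary(de) else
    list(n_total = 0L, n_coexpressed = 0L, percent = NA_real_)
  share <- if (nrow(de)) abundance_summary(de, config$top_n) else
    list(share = c(A = NA_real_, B = NA_real_), ranked = NULL)

  result <- list(
    filter_report = fc$report,
    mappable_totals = mappable_totals,
    class_proportions = class_props,
    length_histogram = length_histogram(fc$tags),
    annotation = anno,
    tier_table = anno$tier_table,
    isomir_table = isomir_table,
    isomir_families = families,
    de_table = de,
    coexpression = coexp,
    abundance_share = share$share,
    top_ranked = share$ranked,
    libraries = libs,
    config = config)
  class(result) <- "mf_pipeline_result"

  if (!is.null(config$outdir)) write_pipeline_result(result, config$outdir)
  result
}

#' Write pipeline tables and a run manifest to a directory
#'
#' @param result An `mf_pipeline_result`.
#' @param outdir Output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_pipeline_result <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(result$filter_report, file.path(outdir, "filter_report.tsv"))
  write_tsv(result$class_proportions,
            file.path(outdir, "class_proportions.tsv"))
  write_tsv(result$length_histogram,
            file.path(outdir, "length_histogram.tsv"))
  write_tsv(result$tier_table, file.path(outdir, "tier_table.tsv"))
  anno <- result$annotation$annotations
  write_tsv(anno[, setdiff(names(anno), "precursor_seq")],
            file.path(outdir, "annotations.tsv"))
  write_tsv(result$isomir_table, file.path(outdir, "isomir_families.tsv"))
  write_tsv(result$de_table, file.path(outdir, "de_table.tsv"))
  manifest <- list(
    package = "mirforge",
    version = as.character(utils::packageVersion("mirforge")),
    seed = result$config$seed,
    libraries = result$libraries,
    mappable_totals = as.list(result$mappable_totals),
    coexpression = result$coexpression,
    abundance_share = as.list(result$abundance_share),
    parameters = result$config[c("min_len", "max_len", "min_count",
                                 "max_mismatch", "flank",
                                 "min_candidate_len", "slop", "max_offset",
                                 "max_subst", "p_threshold", "fc_threshold",
                                 "presence_threshold", "top_n")])
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             file.path(outdir, "manifest.json"))
  invisible(outdir)
}

#' @export
print.mf_pipeline_result <- function(x, ...) {
  cat("mirforge pipeline result\n")
  cat(sprintf("  mappable reads: %s\n",
              paste(sprintf("%s=%d", names(x$mappable_totals),
                            as.integer(x$mappable_totals)),
                    collapse = ", ")))
  print(x$tier_table)
  cat(sprintf("  co-expressed: %d of %d (%.2f%%)\n",
              x$coexpression$n_coexpressed, x$coexpression$n_total,
              x$coexpression$percent))
  cat(sprintf("  DE miRNAs (p < %g): %d\n", x$config$p_threshold,
              sum(x$de_table$is_DE)))
  invisible(x)
}
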