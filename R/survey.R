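#' Survey run configuration
#'
#' Bundles the tunable parameters of the survey workflow with their standard
#' values: a 15-35 nt read window, 20-24 nt Dicer pair search with 2-nt
#' overhangs, 26-30 nt piRNA size class, Ping Pong focal overlap 10, phasing
#' distances 1-9, locus merge gap 500 bp with a 1000 RPM floor, and a 1.96
#' Ping Pong z threshold for strict piRNA locus calls.
#'
#' Exactly one input source must be given: `sim` (a [sim_config()], the
#' synthetic bundle is generated on the fly) or `alignment_files` +
#' `genome_file`.
#'
#' @param sim Optional [sim_config()].
#' @param alignment_files Optional character vector of SAM/BAM/BED paths.
#' @param genome_file FASTA path (required with `alignment_files`).
#' @param min_len,max_len Read length screen (nt).
#' @param dicer_range,pirna_range Size windows (nt).
#' @param overhang Dicer 3' overhang (nt).
#' @param focal_k Ping Pong focal overlap (nt).
#' @param k_max,d_max Histogram extents.
#' @param merge_gap,min_rpm Locus annotation rule.
#' @param z_min Strict piRNA-call Ping Pong z threshold.
#' @param run_sweep Include the merge-gap/RPM threshold sweep.
#' @param seed Integer seed for any randomness in the run.
#' @return A list of class `survey_config`.
#' @export
survey_config <- function(sim = NULL, alignment_files = NULL,
                          genome_file = NULL,
                          min_len = 15L, max_len = 35L,
                          dicer_range = c(20L, 24L),
                          pirna_range = c(26L, 30L), overhang = 2L,
                          focal_k = 10L, k_max = 25L, d_max = 9L,
                          merge_gap = 500L, min_rpm = 1000, z_min = 1.96,
                          run_sweep = TRUE, seed = 1L) {
  if (is.null(sim) == is.null(alignment_files)) {
    stop("give exactly one of `sim` or `alignment_files`")
  }
  if (!is.null(alignment_files) && is.null(genome_file)) {
    stop("`genome_file` is required with `alignment_files`")
  }
  structure(list(sim = sim, alignment_files = alignment_files,
                 genome_file = genome_file, min_len = as.integer(min_len),
                 max_len = as.integer(max_len),
                 dicer_range = as.integer(dicer_range),
                 pirna_range = as.integer(pirna_range),
                 overhang = as.integer(overhang),
                 focal_k = as.integer(focal_k), k_max = as.integer(k_max),
                 d_max = as.integer(d_max),
                 merge_gap = as.integer(merge_gap), min_rpm = min_rpm,
                 z_min = z_min, run_sweep = isTRUE(run_sweep),
                 seed = as.integer(seed)),
            class = "survey_config")
}

#' Run the small-RNA survey workflow
#'
#' Executes the full pipeline on the configured input: load (or simulate)
#' libraries, genome-wide signature statistics per library, locus annotation
#' on the first library (with an optional threshold sweep), per-locus size
#' profiling and classification, and — with two or more samples — the locus
#' count matrix, median-of-ratios normalization and sample PCA.
#'
#' The returned summary is fully determined by the configuration (including
#' its seed); when `out_dir` is given, the summary (`summary.json`), the
#' resolved configuration (`config.json`), the loci (`loci.bed`), histograms
#' and matrices (TSV) are written there.
#'
#' @param config A [survey_config()].
#' @param out_dir Optional output directory.
#' @return The summary, an invisible list; see `summary.json` keys.
#' @export
run_survey <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "survey_config"))
  set.seed(config$seed)

  if (!is.null(config$sim)) {
    sim <- simulate_library(config$sim)
    libraries <- list(sim$library)
    names(libraries) <- sim$library$sample_id
  } else {
    genome <- load_genome(config$genome_file)
    libraries <- lapply(config$alignment_files, load_alignments,
                        genome = genome, min_len = config$min_len,
                        max_len = config$max_len)
    names(libraries) <- vapply(libraries, `[[`, "", "sample_id")
  }

  per_sample <- lapply(libraries, function(lib) {
    prof <- signature_profile(lib, k_max = config$k_max,
                              d_max = config$d_max, focal = config$focal_k)
    pct <- percent_dicer_pairs(lib, size_range = config$dicer_range,
                               overhang = config$overhang)
    list(n_alignments = length(lib$reads), total_mapped = lib$total_mapped,
         percent_dicer_pairs = as.numeric(pct),
         n_dicer_pairs = attr(pct, "n_pairs"),
         pingpong_z = prof$pingpong_z, phasing_z = prof$phasing_z,
         first_u_fraction = prof$first_u_fraction,
         size_distribution = as.list(size_distribution(
           lib, config$min_len, config$max_len)))
  })

  lib1 <- libraries[[1]]
  loci <- annotate_loci(lib1, merge_gap = config$merge_gap,
                        min_rpm = config$min_rpm)
  sweep_df <- if (config$run_sweep) threshold_sweep(lib1) else NULL

  classes <- NULL; size_m <- NULL; sig_df <- NULL
  if (length(loci) > 0L) {
    size_m <- locus_size_matrix(loci, lib1,
                                len_range = c(config$min_len,
                                              config$max_len))
    sig_df <- locus_signatures(loci, lib1, k_max = config$k_max,
                               d_max = config$d_max)
    keep <- rowSums(size_m) > 0
    classes <- classify_loci(size_m[keep, , drop = FALSE], sig_df,
                             pirna_range = config$pirna_range,
                             z_min = config$z_min)
    strict <- classify_loci(size_m[keep, , drop = FALSE], sig_df,
                            pirna_range = config$pirna_range,
                            strict = TRUE, z_min = config$z_min)
  }

  expr <- NULL
  if (length(libraries) >= 2L && length(loci) > 0L) {
    cm <- count_matrix(loci, libraries)
    norm <- normalize_counts(cm)
    expr <- list(counts = cm, normalized = norm,
                 pca = if (ncol(cm) >= 2L) srna_pca(norm) else NULL)
  }

  class_counts <- if (!is.null(classes)) as.list(table(classes$class))
                  else list()
  summary <- list(
    parameters = unclass(config)[setdiff(names(config), "sim")],
    sim_seed = if (!is.null(config$sim)) config$sim$seed else NULL,
    samples = per_sample,
    n_loci = length(loci),
    total_locus_bp = sum(width(loci)),
    genome_coverage = sum(width(loci)) /
      sum(as.numeric(lib1$seqlengths)),
    class_counts = class_counts,
    n_pirna_like_strict = if (!is.null(classes))
      sum(strict$class == "pirna_like") else 0L,
    pca_explained_variance = if (!is.null(expr) && !is.null(expr$pca))
      expr$pca$explained_variance else NULL)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    cfg <- unclass(config)
    cfg$sim <- if (!is.null(cfg$sim)) unclass(cfg$sim) else NULL
    write_json(cfg, file.path(out_dir, "config.json"),
               auto_unbox = TRUE, pretty = TRUE, digits = 10)
    write_json(summary, file.path(out_dir, "summary.json"),
               auto_unbox = TRUE, pretty = TRUE, digits = 10)
    write_loci_bed(loci, file.path(out_dir, "loci.bed"))
    if (!is.null(sweep_df)) {
      write.table(sweep_df, file.path(out_dir, "threshold_sweep.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(classes)) {
      write.table(classes, file.path(out_dir, "locus_classes.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      ord <- cluster_rows(row_zscore(size_m))
      zm <- row_zscore(size_m)[ord, , drop = FALSE]
      write.table(data.frame(locus_id = rownames(zm), zm,
                             check.names = FALSE),
                  file.path(out_dir, "size_matrix_z.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(expr)) {
      write.table(data.frame(locus_id = rownames(expr$counts), expr$counts,
                             check.names = FALSE),
                  file.path(out_dir, "count_matrix.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(summary)
}
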