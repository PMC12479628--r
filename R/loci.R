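#' Coverage islands
#'
#' Maximal genomic intervals in which per-base read coverage (copy-weighted,
#' both strands pooled) reaches `min_depth`. These raw islands are the seeds
#' of small-RNA locus annotation; gap-merging and RPM filtering do the
#' shaping.
#'
#' @param library An [srna_library].
#' @param min_depth Minimum per-base coverage (default 1, the most inclusive
#'   seeding; downstream RPM filtering removes low-confidence regions).
#' @return A sorted, non-overlapping unstranded `GRanges`.
#' @export
coverage_islands <- function(library, min_depth = 1L) {
  stopifnot(inherits(library, "srna_library"))
  if (min_depth < 1L) stop("min_depth must be >= 1")
  cov <- coverage(library$reads, weight = as.numeric(read_copy(library$reads)))
  isl <- slice(cov, lower = min_depth, rangesOnly = TRUE)
  gr <- methods::as(isl, "GRanges")
  seqlevels(gr) <- names(library$seqlengths)
  seqlengths(gr) <- library$seqlengths
  sort(gr)
}

#' Merge nearby regions
#'
#' Fuses intervals on the same chromosome whose gap is at most `max_gap` bp.
#' Merging nearby features avoids accidentally splitting one read cluster
#' into several candidate loci.
#'
#' @param regions A `GRanges` of non-overlapping regions.
#' @param max_gap Largest gap (bp) still merged.
#' @return A sorted, non-overlapping `GRanges`.
#' @export
merge_regions <- function(regions, max_gap) {
  if (max_gap < 0L) stop("max_gap must be >= 0")
  reduce(sort(regions), min.gapwidth = max_gap + 1L, ignore.strand = TRUE)
}

# Copy-weighted read count per region, assigning each read by its 5' end.
region_counts <- function(regions, library) {
  hits <- findOverlaps(five_prime_points(library$reads), regions,
                       ignore.strand = TRUE)
  counts <- numeric(length(regions))
  if (length(hits) > 0L) {
    tab <- tapply(read_copy(library$reads)[queryHits(hits)],
                  subjectHits(hits), sum)
    counts[as.integer(names(tab))] <- tab
  }
  counts
}

#' Trim merged regions to supported boundaries
#'
#' Gap-merging fuses every coverage island within reach, so a single stray
#' background alignment near a locus can extend its boundaries by up to the
#' merge gap. This step trims each merged region to the span of its
#' outermost coverage island holding at least `min_island_reads`
#' (copy-weighted, 5'-end assigned) alignments — a singleton flanking
#' alignment is not treated as boundary evidence. Regions with no supported
#' island are dropped.
#'
#' @param regions Merged candidate regions (`GRanges`).
#' @param library An [srna_library].
#' @param min_island_reads Minimum alignments for a boundary island
#'   (default 2); 1 disables trimming.
#' @return A `GRanges` of trimmed regions (possibly fewer than the input).
#' @export
trim_regions <- function(regions, library, min_island_reads = 2L) {
  if (min_island_reads <= 1L || length(regions) == 0L) return(regions)
  islands <- coverage_islands(library)
  good <- islands[region_counts(islands, library) >= min_island_reads]
  hits <- findOverlaps(good, regions, ignore.strand = TRUE)
  if (length(hits) == 0L) return(regions[0])
  s <- tapply(start(good)[queryHits(hits)], subjectHits(hits), min)
  e <- tapply(end(good)[queryHits(hits)], subjectHits(hits), max)
  idx <- as.integer(names(s))
  out <- GRanges(seqnames(regions)[idx], IRanges(unname(s), unname(e)),
                 seqinfo = seqinfo(regions))
  sort(out)
}

#' Filter candidate regions into annotated loci
#'
#' Assigns every read to the region containing its 5' end (so each read is
#' counted in exactly one locus), computes region RPM against the library's
#' total mapped count, and keeps regions at or above the threshold.
#'
#' @param regions Candidate regions (`GRanges`), e.g. from
#'   [coverage_islands()] + [merge_regions()].
#' @param library An [srna_library].
#' @param min_rpm RPM threshold (default 1000).
#' @param min_count Raw-count threshold alternative; when non-`NULL` it is
#'   used instead of `min_rpm`.
#' @return A sorted `GRanges` of loci with metadata columns `locus_id`,
#'   `read_count`, `rpm`.
#' @export
filter_loci <- function(regions, library, min_rpm = 1000, min_count = NULL) {
  stopifnot(inherits(library, "srna_library"))
  regions <- sort(regions)
  counts <- region_counts(regions, library)
  rpms <- rpm(counts, library$total_mapped)
  keep <- if (!is.null(min_count)) counts >= min_count else rpms >= min_rpm
  keep <- keep & counts >= 1
  loci <- granges(regions)[keep]
  mcols(loci)$locus_id <- sprintf("locus_%05d", seq_along(loci))
  mcols(loci)$read_count <- counts[keep]
  mcols(loci)$rpm <- rpms[keep]
  loci
}

#' Annotate small-RNA-expressing loci
#'
#' The full annotation rule: coverage islands, merged within `merge_gap` bp,
#' trimmed to supported boundaries, filtered at `min_rpm`.
#'
#' @inheritParams filter_loci
#' @inheritParams trim_regions
#' @param merge_gap Merge gap in bp (default 500).
#' @param min_depth Island seeding depth (default 1).
#' @return A `GRanges` of loci as in [filter_loci()].
#' @export
annotate_loci <- function(library, merge_gap = 500L, min_rpm = 1000,
                          min_depth = 1L, min_count = NULL,
                          min_island_reads = 2L) {
  islands <- coverage_islands(library, min_depth)
  merged <- merge_regions(islands, merge_gap)
  trimmed <- trim_regions(merged, library, min_island_reads)
  filter_loci(trimmed, library, min_rpm = min_rpm, min_count = min_count)
}

#' Sweep merge-gap and RPM thresholds
#'
#' Recomputes the locus annotation over a grid of merge gaps and RPM
#' thresholds, reporting the locus count and the fraction of the genome
#' covered for each combination — the optimization used to pick the final
#' annotation rule.
#'
#' @param library An [srna_library].
#' @param gaps Merge gaps (bp); default the decade grid 0/5/50/500/5000/50000.
#' @param rpm_thresholds RPM thresholds; default a decade grid from 0 to 1e6.
#' @inheritParams trim_regions
#' @return A data.frame with columns `merge_gap`, `min_rpm`, `n_loci`,
#'   `total_locus_bp`, `genome_coverage` (total locus bp over total genome
#'   bp).
#' @export
threshold_sweep <- function(library,
                            gaps = c(0L, 5L, 50L, 500L, 5000L, 50000L),
                            rpm_thresholds = c(0, 10^(0:6)),
                            min_island_reads = 2L) {
  stopifnot(inherits(library, "srna_library"),
            length(gaps) > 0L, length(rpm_thresholds) > 0L)
  genome_bp <- sum(as.numeric(library$seqlengths))
  islands <- coverage_islands(library)
  out <- list()
  for (gap in gaps) {
    merged <- trim_regions(merge_regions(islands, gap), library,
                           min_island_reads)
    counts <- region_counts(merged, library)
    rpms <- rpm(counts, library$total_mapped)
    for (thr in rpm_thresholds) {
      keep <- rpms >= thr & counts >= 1
      out[[length(out) + 1L]] <- data.frame(
        merge_gap = gap, min_rpm = thr, n_loci = sum(keep),
        total_locus_bp = sum(width(merged)[keep]),
        genome_coverage = sum(width(merged)[keep]) / genome_bp)
    }
  }
  do.call(rbind, out)
}

#' Write loci as BED6
#'
#' @param loci `GRanges` from [filter_loci()] or [annotate_loci()].
#' @param path Output path. Score column carries the read count.
#' @return `path`, invisibly.
#' @export
write_loci_bed <- function(loci, path) {
  df <- data.frame(
    chrom = as.character(seqnames(loci)),
    start = start(loci) - 1L,
    end = end(loci),
    name = mcols(loci)$locus_id,
    score = mcols(loci)$read_count,
    strand = ".")
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
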