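#' Construct a small-RNA library
#'
#' An `srna_library` bundles a sample's aligned reads with the bookkeeping the
#' pipeline needs: the total mapped count used as the RPM denominator and the
#' chromosome lengths of the reference the reads were mapped to.
#'
#' @param reads A [GenomicRanges::GRanges] of aligned reads. Metadata columns
#'   `copy` (integer multiplicity, default 1) and `first_nt` (5' nucleotide in
#'   RNA alphabet) are added if missing (`first_nt` as `NA`).
#' @param seqlens Named integer vector of chromosome lengths. Defaults to the
#'   `seqlengths` of `reads`, which must then be complete.
#' @param sample_id Sample name.
#' @param meta List of provenance metadata (input record counts, filters
#'   applied, pre-filter totals).
#'
#' @return An object of class `srna_library`: a list with elements
#'   `sample_id`, `reads`, `total_mapped` (sum of `copy`), `seqlengths`,
#'   `meta`.
#' @export
srna_library <- function(reads, seqlens = NULL, sample_id = "sample",
                         meta = list()) {
  stopifnot(methods::is(reads, "GRanges"))
  if (is.null(seqlens)) seqlens <- seqlengths(reads)
  if (any(is.na(seqlens)) || is.null(names(seqlens))) {
    stop("chromosome lengths must be known for every sequence")
  }
  if (!all(as.character(seqnames(reads)) %in% names(seqlens))) {
    stop("reads on sequences absent from the genome")
  }
  if (is.null(mcols(reads)$copy)) mcols(reads)$copy <- 1L
  if (is.null(mcols(reads)$first_nt)) mcols(reads)$first_nt <- NA_character_
  if (any(mcols(reads)$copy < 1L)) stop("read copy numbers must be >= 1")
  seqlevels(reads) <- names(seqlens)
  seqlengths(reads) <- seqlens
  bad <- start(reads) < 1L | end(reads) > seqlens[as.character(seqnames(reads))]
  if (any(bad)) stop(sum(bad), " read(s) extend beyond chromosome bounds")
  structure(
    list(sample_id = sample_id, reads = reads,
         total_mapped = sum(mcols(reads)$copy),
         seqlengths = seqlens, meta = meta),
    class = "srna_library"
  )
}

#' @export
print.srna_library <- function(x, ...) {
  cat("srna_library '", x$sample_id, "': ", length(x$reads),
      " alignments, total mapped ", x$total_mapped, ", ",
      length(x$seqlengths), " sequence(s)\n", sep = "")
  invisible(x)
}

#' @export
length.srna_library <- function(x) length(x$reads)

#' Subset a library to reads overlapping a region
#'
#' @param library An [srna_library].
#' @param region A `GRanges` of one or more regions; reads whose 5' end falls
#'   inside any region are kept (the same containment rule used for locus
#'   read assignment).
#' @return An `srna_library` with the subset of reads; `total_mapped` is kept
#'   from the parent library so RPM values stay on the library scale.
#' @export
subset_library <- function(library, region) {
  stopifnot(inherits(library, "srna_library"))
  hits <- findOverlaps(five_prime_points(library$reads), region,
                       ignore.strand = TRUE)
  reads <- library$reads[unique(queryHits(hits))]
  out <- srna_library(reads, library$seqlengths, library$sample_id,
                      library$meta)
  out$total_mapped <- library$total_mapped
  out
}

# 1-width GRanges at each read's 5' end (strand-aware)
five_prime_points <- function(reads) {
  pos <- ifelse(as.character(strand(reads)) == "-", end(reads), start(reads))
  GRanges(seqnames(reads), IRanges(pos, width = 1L), strand = strand(reads),
          seqinfo = seqinfo(reads))
}

#' Reads-per-million scaling
#'
#' @param count Raw read count(s).
#' @param total_mapped Library total mapped count (the RPM denominator).
#' @return `count * 1e6 / total_mapped`.
#' @examples
#' rpm(5000, 1e6)  # 5000
#' @export
rpm <- function(count, total_mapped) {
  if (length(total_mapped) != 1L || is.na(total_mapped) || total_mapped <= 0) {
    stop("total_mapped must be a single positive count")
  }
  count * 1e6 / total_mapped
}
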