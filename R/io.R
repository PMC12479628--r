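#' Load a reference genome from FASTA
#'
#' Sequences are uppercased on load so base lookups are case-insensitive.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] keyed by record name.
#' @export
load_genome <- function(path) {
  genome <- tryCatch(readDNAStringSet(path),
                     error = function(e) stop("failed to parse FASTA '", path,
                                              "': ", conditionMessage(e)))
  if (length(genome) == 0L) stop("FASTA '", path, "' contains no records")
  # keep only the first word of each header, as aligners do
  names(genome) <- sub("\\s.*$", "", names(genome))
  DNAStringSet(toupper(genome))
}

# 5' nucleotide of each read in read orientation, RNA alphabet (U not T).
# For minus-strand reads this is the reverse complement of the genome base
# under the rightmost read position.
compute_first_nt <- function(reads, genome) {
  out <- character(length(reads))
  minus <- as.character(strand(reads)) == "-"
  pos <- ifelse(minus, end(reads), start(reads))
  for (chr in unique(as.character(seqnames(reads)))) {
    idx <- which(as.character(seqnames(reads)) == chr)
    s <- as.character(genome[[chr]])
    base <- substring(s, pos[idx], pos[idx])
    flip <- minus[idx]
    base[flip] <- chartr("ACGTN", "TGCAN", base[flip])
    out[idx] <- base
  }
  chartr("T", "U", out)
}

#' Load small-RNA alignments into a library
#'
#' Reads SAM, BAM or BED6 alignments, keeps mapped records whose length lies
#' in `[min_len, max_len]`, and computes each read's 5' nucleotide from the
#' genome. SAM/BAM 1-based records and BED 0-based records are both
#' represented internally as 1-based closed `GRanges`. Records whose CIGAR
#' contains anything but a single match run (indels, splices, clips) are
#' skipped with a warning: small-RNA alignments are ungapped.
#'
#' @param path Alignment file (`.sam`, `.bam`, `.bed`).
#' @param genome A [Biostrings::DNAStringSet] from [load_genome()].
#' @param min_len,max_len Retained read length window in nt (default 15-35).
#' @param sample_id Sample name; defaults to the file name.
#' @param format `"auto"` (by extension), `"sam"`, `"bam"` or `"bed"`.
#' @return An [srna_library]. `meta` records `n_input` (mapped records seen),
#'   `n_skipped_cigar`, `n_length_filtered`, and `prefilter_total` (sum of
#'   copies before the length screen), so statistics that want an unfiltered
#'   denominator can use it.
#' @export
load_alignments <- function(path, genome, min_len = 15L, max_len = 35L,
                            sample_id = NULL,
                            format = c("auto", "sam", "bam", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     sam = "sam", bam = "bam", bed = "bed",
                     stop("cannot guess alignment format of '", path, "'"))
  }
  if (min_len > max_len) stop("min_len must be <= max_len")
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))
  seqlens <- setNames(width(genome), names(genome))

  if (format == "bed") {
    gr <- import(path, format = "BED")
    if (!all(as.character(seqnames(gr)) %in% names(genome))) {
      bad <- setdiff(unique(as.character(seqnames(gr))), names(genome))
      stop("alignment on unknown sequence(s): ", paste(bad, collapse = ", "))
    }
    copy <- mcols(gr)$score
    copy <- if (is.null(copy)) rep(1L, length(gr)) else as.integer(copy)
    copy[is.na(copy) | copy < 1L] <- 1L
    reads <- granges(gr)
    mcols(reads)$copy <- copy
    n_skipped <- 0L
  } else {
    bam <- path
    if (format == "sam") {
      dest <- tempfile(fileext = "")
      bam <- suppressMessages(asBam(path, dest, overwrite = TRUE,
                                    indexDestination = FALSE))
    }
    res <- scanBam(bam, param = ScanBamParam(
      what = c("rname", "pos", "strand", "cigar"),
      flag = scanBamFlag(isUnmappedQuery = FALSE)))[[1]]
    cig_ok <- grepl("^[0-9]+M$", res$cigar)
    n_skipped <- sum(!cig_ok)
    if (n_skipped > 0L) {
      warning(n_skipped, " record(s) with indel/splice/clip CIGAR skipped")
    }
    rname <- as.character(res$rname)[cig_ok]
    if (!all(rname %in% names(genome))) {
      bad <- setdiff(unique(rname), names(genome))
      stop("alignment on unknown sequence(s): ", paste(bad, collapse = ", "))
    }
    w <- as.integer(sub("M$", "", res$cigar[cig_ok]))
    reads <- GRanges(rname,
                     IRanges(res$pos[cig_ok], width = w),
                     strand = as.character(res$strand)[cig_ok])
    mcols(reads)$copy <- 1L
  }

  n_input <- length(reads)
  prefilter_total <- sum(mcols(reads)$copy)
  if (any(as.character(strand(reads)) == "*")) {
    stop("alignments must be stranded")
  }
  keep <- width(reads) >= min_len & width(reads) <= max_len
  n_len_filtered <- sum(!keep)
  reads <- reads[keep]
  mcols(reads)$first_nt <- compute_first_nt(reads, genome)
  srna_library(reads, seqlens, sample_id,
               meta = list(n_input = n_input,
                           n_skipped_cigar = n_skipped,
                           n_length_filtered = n_len_filtered,
                           prefilter_total = prefilter_total,
                           min_len = min_len, max_len = max_len))
}

#' Read-size distribution of a library
#'
#' @param library An [srna_library].
#' @param min_len,max_len Length window of the returned vector.
#' @return Named integer vector of summed copy numbers per read length; the
#'   sum equals the number of (copy-weighted) reads inside the window.
#' @export
size_distribution <- function(library, min_len = 15L, max_len = 35L) {
  stopifnot(inherits(library, "srna_library"), min_len <= max_len)
  lens <- seq.int(min_len, max_len)
  out <- setNames(numeric(length(lens)), lens)
  w <- width(library$reads)
  keep <- w >= min_len & w <= max_len
  if (any(keep)) {
    tab <- tapply(mcols(library$reads)$copy[keep], w[keep], sum)
    out[names(tab)] <- tab
  }
  out
}

#' Write a library's alignments as BED6
#'
#' Coordinates follow the BED convention (0-based half-open); the score
#' column carries the copy number.
#'
#' @param library An [srna_library].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(library, path) {
  reads <- library$reads
  df <- data.frame(
    chrom = as.character(seqnames(reads)),
    start = start(reads) - 1L,
    end = end(reads),
    name = sprintf("read_%06d", seq_along(reads)),
    score = mcols(reads)$copy,
    strand = as.character(strand(reads)))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a library's alignments as SAM
#'
#' Emits a minimal ungapped SAM (header `@SQ` lines from the library's
#' chromosome lengths, one `<len>M` record per alignment, sequence filled in
#' from the genome, minus-strand records reverse-complemented as SAM
#' requires). Each copy-weighted alignment is written `copy` times so the
#' file round-trips through [load_alignments()] as an identical multiset.
#'
#' @param library An [srna_library].
#' @param genome The reference [Biostrings::DNAStringSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(library, genome, path) {
  reads <- library$reads
  reads <- rep(reads, mcols(reads)$copy)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(library$seqlengths),
                     library$seqlengths), con)
  if (length(reads) > 0L) {
    seqs <- character(length(reads))
    for (chr in unique(as.character(seqnames(reads)))) {
      idx <- which(as.character(seqnames(reads)) == chr)
      s <- as.character(genome[[chr]])
      seqs[idx] <- substring(s, start(reads)[idx], end(reads)[idx])
    }
    minus <- as.character(strand(reads)) == "-"
    seqs[minus] <- as.character(
      Biostrings::reverseComplement(DNAStringSet(seqs[minus])))
    writeLines(sprintf("read_%06d\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*",
                       seq_along(reads), ifelse(minus, 16L, 0L),
                       as.character(seqnames(reads)), start(reads),
                       width(reads), seqs), con)
  }
  invisible(path)
}
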