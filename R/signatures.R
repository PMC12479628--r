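#' 5'-5' overlap histogram of opposite-strand read pairs
#'
#' For every plus-strand read P and minus-strand read M on the same
#' chromosome that physically overlap, the 5'-5' overlap is the number of
#' bases from P's 5' end to M's 5' end inclusive. Ping Pong piRNA pairs show
#' a sharp peak at 10; Dicer siRNA duplexes populate bins near the read
#' length. Bin k accumulates `copy(P) * copy(M)`.
#'
#' @param reads A `GRanges` of reads (with `copy` metadata) or an
#'   [srna_library].
#' @param k_max Largest overlap tracked (default 25).
#' @return Named numeric vector of length `k_max`, names `"1"..k_max`.
#' @export
overlap_histogram <- function(reads, k_max = 25L) {
  if (inherits(reads, "srna_library")) reads <- reads$reads
  if (k_max < 1L) stop("k_max must be >= 1")
  copy <- read_copy(reads)
  plus <- which(as.character(strand(reads)) == "+")
  minus <- which(as.character(strand(reads)) == "-")
  h <- setNames(numeric(k_max), seq_len(k_max))
  if (length(plus) == 0L || length(minus) == 0L) return(h)
  hits <- findOverlaps(granges(reads)[plus], granges(reads)[minus],
                       ignore.strand = TRUE)
  # overlapping opposite-strand pair: k = 5'-5' span = end(M) - start(P) + 1
  k <- end(reads)[minus[subjectHits(hits)]] -
    start(reads)[plus[queryHits(hits)]] + 1L
  w <- copy[plus[queryHits(hits)]] * copy[minus[subjectHits(hits)]]
  keep <- k >= 1L & k <= k_max
  if (any(keep)) {
    tab <- tapply(w[keep], k[keep], sum)
    h[names(tab)] <- h[names(tab)] + tab
  }
  h
}

# z of one focal histogram bin against all remaining bins (sample sd).
# NA when the background is flat (sd 0) -- the score is then undefined.
focal_bin_zscore <- function(hist, focal) {
  if (length(hist) < focal || length(hist) < 2L) {
    stop("histogram too short for focal bin ", focal)
  }
  bg <- hist[-focal]
  s <- sd(bg)
  if (is.na(s) || s == 0) return(NA_real_)
  unname((hist[focal] - mean(bg)) / s)
}

#' Ping Pong z-score
#'
#' z of the 10-nt overlap bin against all other bins of the overlap
#' histogram (background mean and sample standard deviation). `NA` when the
#' background has zero variance, in which case the score is undefined rather
#' than infinite.
#'
#' @param hist Overlap histogram from [overlap_histogram()] (`k_max >= 11`).
#' @param focal Focal overlap (default 10).
#' @return A single numeric z-score, or `NA` if undefined.
#' @export
pingpong_zscore <- function(hist, focal = 10L) {
  if (length(hist) < 11L) stop("overlap histogram must extend past bin 10")
  focal_bin_zscore(hist, focal)
}

#' Find Dicer duplex read pairs
#'
#' Searches a library for opposite-strand read pairs with the geometry of an
#' RNase III duplex product: both reads of Dicer size and a 3' overhang of
#' exactly `overhang` nt at both duplex ends (`start(P) - start(M) ==
#' overhang` and `end(P) - end(M) == overhang`). With `ends = "either"` a
#' single matching overhang suffices (the pair must still physically
#' overlap). Each unordered pair is reported once.
#'
#' @param library An [srna_library] (or a read `GRanges`).
#' @param size_range Read length window for both mates (default 20-24 nt).
#' @param overhang 3' overhang length (default 2 nt).
#' @param ends `"both"` (default) or `"either"`.
#' @return A data.frame with one row per pair: `chrom`, `plus_start`,
#'   `plus_end`, `minus_start`, `minus_end` (1-based closed), `plus_idx`,
#'   `minus_idx` (indices into the library's reads), `weight`
#'   (`copy(P) * copy(M)`).
#' @export
find_dicer_pairs <- function(library, size_range = c(20L, 24L),
                             overhang = 2L, ends = c("both", "either")) {
  ends <- match.arg(ends)
  reads <- if (inherits(library, "srna_library")) library$reads else library
  if (overhang < 0L) stop("overhang must be >= 0")
  if (size_range[1] > size_range[2]) stop("size_range is inverted")
  copy <- read_copy(reads)
  w <- width(reads)
  in_size <- w >= size_range[1] & w <= size_range[2]
  plus <- which(as.character(strand(reads)) == "+" & in_size)
  minus <- which(as.character(strand(reads)) == "-" & in_size)
  empty <- data.frame(chrom = character(), plus_start = integer(),
                      plus_end = integer(), minus_start = integer(),
                      minus_end = integer(), plus_idx = integer(),
                      minus_idx = integer(), weight = numeric())
  if (length(plus) == 0L || length(minus) == 0L) return(empty)
  hits <- findOverlaps(granges(reads)[plus], granges(reads)[minus],
                       ignore.strand = TRUE)
  ip <- plus[queryHits(hits)]; im <- minus[subjectHits(hits)]
  d5 <- start(reads)[ip] - start(reads)[im]  # M's 3' overhang
  d3 <- end(reads)[ip] - end(reads)[im]      # P's 3' overhang
  keep <- if (ends == "both") d5 == overhang & d3 == overhang
          else d5 == overhang | d3 == overhang
  ip <- ip[keep]; im <- im[keep]
  if (length(ip) == 0L) return(empty)
  data.frame(chrom = as.character(seqnames(reads))[ip],
             plus_start = start(reads)[ip], plus_end = end(reads)[ip],
             minus_start = start(reads)[im], minus_end = end(reads)[im],
             plus_idx = ip, minus_idx = im,
             weight = copy[ip] * copy[im])
}

#' Percentage of Dicer pairs in a library
#'
#' The number of Dicer duplex pairs divided by the total alignments in the
#' library, times 100. The default denominator is the library's retained
#' (length-screened) total mapped count; the pre-filter total, when recorded
#' by [load_alignments()], is attached for transparency.
#'
#' @inheritParams find_dicer_pairs
#' @param denominator `"filtered"` (default, the library's `total_mapped`)
#'   or `"prefilter"` (`meta$prefilter_total` when available).
#' @return A single percentage, with attributes `n_pairs`, `n_reads_in_pairs`
#'   (distinct alignments participating in at least one pair) and
#'   `denominator`.
#' @export
percent_dicer_pairs <- function(library, size_range = c(20L, 24L),
                                overhang = 2L,
                                denominator = c("filtered", "prefilter")) {
  stopifnot(inherits(library, "srna_library"))
  denominator <- match.arg(denominator)
  total <- if (denominator == "prefilter" &&
               !is.null(library$meta$prefilter_total))
    library$meta$prefilter_total else library$total_mapped
  if (total <= 0) stop("library is empty")
  pairs <- find_dicer_pairs(library, size_range, overhang)
  pct <- 100 * nrow(pairs) / total
  attr(pct, "n_pairs") <- nrow(pairs)
  attr(pct, "n_reads_in_pairs") <-
    length(unique(c(pairs$plus_idx, pairs$minus_idx)))
  attr(pct, "denominator") <- total
  pct
}

# Weighted count of position pairs at each offset d = b - a, d in 1..d_max.
# a/b are genomic positions, wa/wb their copy weights.
gap_pair_counts <- function(a, wa, b, wb, d_max) {
  out <- numeric(d_max)
  if (length(a) == 0L || length(b) == 0L) return(out)
  sa <- tapply(wa, a, sum); sb <- tapply(wb, b, sum)
  pa <- as.integer(names(sa)); pb <- as.integer(names(sb))
  for (d in seq_len(d_max)) {
    m <- match(pa + d, pb)
    ok <- !is.na(m)
    if (any(ok)) out[d] <- sum(sa[ok] * sb[m[ok]])
  }
  out
}

#' Phasing distance histogram
#'
#' For same-strand read pairs (upstream U, downstream D in the 5'-to-3'
#' orientation of their strand), the phasing distance is the number of bases
#' from U's 3' end to D's 5' end, so that d = 1 means immediately adjacent
#' (head-to-tail). Zucchini-phased piRNA trains show a peak at d = 1. By
#' default only downstream reads whose first nucleotide is U contribute, as
#' Zucchini cleavage at uridines dictates.
#'
#' @param reads A `GRanges` with `first_nt`/`copy` metadata or an
#'   [srna_library].
#' @param d_max Largest distance tracked (default 9).
#' @param require_1U Restrict downstream reads to 1U reads (default TRUE).
#' @return Named numeric vector over d = 1..`d_max`.
#' @export
phasing_histogram <- function(reads, d_max = 9L, require_1U = TRUE) {
  if (inherits(reads, "srna_library")) reads <- reads$reads
  if (d_max < 1L) stop("d_max must be >= 1")
  copy <- read_copy(reads)
  first_nt <- mcols(reads)$first_nt
  down_ok <- if (require_1U) {
    if (is.null(first_nt)) stop("reads lack first_nt; load against a genome")
    !is.na(first_nt) & first_nt == "U"
  } else rep(TRUE, length(reads))
  h <- setNames(numeric(d_max), seq_len(d_max))
  chrom <- as.character(seqnames(reads))
  str <- as.character(strand(reads))
  for (chr in unique(chrom)) {
    for (s in c("+", "-")) {
      i <- which(chrom == chr & str == s)
      if (length(i) < 2L) next
      dn <- i[down_ok[i]]
      if (s == "+") {
        # d = start(D) - end(U)
        h <- h + gap_pair_counts(end(reads)[i], copy[i],
                                 start(reads)[dn], copy[dn], d_max)
      } else {
        # d = start(U) - end(D)
        h <- h + gap_pair_counts(end(reads)[dn], copy[dn],
                                 start(reads)[i], copy[i], d_max)
      }
    }
  }
  h
}

#' Phasing z-score
#'
#' z of the distance-1 (head-to-tail) bin against distances 2..`d_max`,
#' using the same background-mean / sample-sd contract as
#' [pingpong_zscore()]. `NA` when the background variance is zero.
#'
#' @param hist Phasing histogram from [phasing_histogram()].
#' @return A single numeric z-score, or `NA` if undefined.
#' @export
phasing_zscore <- function(hist) {
  if (length(hist) < 2L) stop("phasing histogram needs >= 2 bins")
  focal_bin_zscore(hist, 1L)
}

#' Fraction of reads starting with a given nucleotide
#'
#' @param reads A `GRanges` with `first_nt`/`copy` metadata or an
#'   [srna_library].
#' @param nucleotide RNA-space nucleotide (default `"U"`).
#' @return Copy-weighted fraction of reads whose 5' nucleotide matches.
#' @export
first_nt_fraction <- function(reads, nucleotide = "U") {
  if (inherits(reads, "srna_library")) reads <- reads$reads
  if (length(reads) == 0L) stop("empty read set")
  first_nt <- mcols(reads)$first_nt
  if (is.null(first_nt)) stop("reads lack first_nt; load against a genome")
  copy <- read_copy(reads)
  sum(copy[!is.na(first_nt) & first_nt == nucleotide]) / sum(copy)
}

#' Full signature profile of a read set
#'
#' Convenience wrapper computing the overlap and phasing histograms with
#' their z-scores and the 1U fraction in one call.
#'
#' @inheritParams overlap_histogram
#' @inheritParams phasing_histogram
#' @param focal Ping Pong focal overlap (default 10).
#' @return A list of class `signature_profile`: `overlap_hist`,
#'   `pingpong_z`, `phasing_hist`, `phasing_z`, `first_u_fraction`,
#'   `n_reads`.
#' @export
signature_profile <- function(reads, k_max = 25L, d_max = 9L,
                              require_1U = TRUE, focal = 10L) {
  if (inherits(reads, "srna_library")) reads <- reads$reads
  oh <- overlap_histogram(reads, k_max)
  ph <- phasing_histogram(reads, d_max, require_1U)
  structure(list(
    overlap_hist = oh,
    pingpong_z = pingpong_zscore(oh, focal),
    phasing_hist = ph,
    phasing_z = phasing_zscore(ph),
    first_u_fraction = if (length(reads)) first_nt_fraction(reads) else NA,
    n_reads = length(reads)), class = "signature_profile")
}

#' @export
print.signature_profile <- function(x, ...) {
  cat("signature_profile:", x$n_reads, "reads\n")
  cat("  ping-pong z (10-nt overlap):", format(x$pingpong_z, digits = 3),
      "\n")
  cat("  phasing z (distance 1):    ", format(x$phasing_z, digits = 3), "\n")
  cat("  1U fraction:               ",
      format(x$first_u_fraction, digits = 3), "\n")
  invisible(x)
}

read_copy <- function(reads) {
  copy <- mcols(reads)$copy
  if (is.null(copy)) rep(1, length(reads)) else as.numeric(copy)
}
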