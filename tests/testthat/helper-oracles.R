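# Independent brute-force oracles and small fixtures. Everything here is
# written against the definitions directly (O(n^2) all-pairs loops,
# per-base coverage scans) and never calls the package's optimized paths.

# Build a read GRanges from parallel vectors (1-based closed coords).
make_reads <- function(chrom, start, end, strand, first_nt = NA_character_,
                       copy = 1L, seqlens = NULL) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                               strand = strand)
  S4Vectors::mcols(gr)$copy <- rep_len(as.integer(copy), length(gr))
  S4Vectors::mcols(gr)$first_nt <- rep_len(first_nt, length(gr))
  if (!is.null(seqlens)) {
    GenomeInfoDb::seqlevels(gr) <- names(seqlens)
    GenomeInfoDb::seqlengths(gr) <- seqlens
  }
  gr
}

# Random read set on a toy genome, mixed strands and lengths.
random_reads <- function(n, seqlens = c(chrA = 5000L, chrB = 3000L),
                         len_range = c(15L, 32L)) {
  chrom <- sample(names(seqlens), n, replace = TRUE)
  len <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  start <- vapply(seq_len(n), function(i) {
    sample.int(seqlens[[chrom[i]]] - len[i], 1L)
  }, integer(1))
  make_reads(chrom, start, start + len - 1L,
             sample(c("+", "-"), n, replace = TRUE),
             first_nt = sample(c("A", "C", "G", "U"), n, replace = TRUE),
             copy = sample(1:3, n, replace = TRUE), seqlens = seqlens)
}

as_df <- function(reads) {
  fn <- S4Vectors::mcols(reads)$first_nt
  if (is.null(fn)) fn <- rep(NA_character_, length(reads))
  cp <- S4Vectors::mcols(reads)$copy
  if (is.null(cp)) cp <- rep(1, length(reads))
  data.frame(chrom = as.character(GenomicRanges::seqnames(reads)),
             start = BiocGenerics::start(reads),
             end = BiocGenerics::end(reads),
             strand = as.character(BiocGenerics::strand(reads)),
             copy = as.numeric(cp),
             first_nt = fn)
}

# O(n^2) 5'-5' overlap histogram of overlapping opposite-strand pairs.
brute_overlap_hist <- function(reads, k_max = 25L) {
  df <- as_df(reads)
  h <- stats::setNames(numeric(k_max), seq_len(k_max))
  p <- df[df$strand == "+", ]
  m <- df[df$strand == "-", ]
  for (i in seq_len(nrow(p))) for (j in seq_len(nrow(m))) {
    if (p$chrom[i] != m$chrom[j]) next
    if (m$start[j] > p$end[i]) next            # must physically overlap
    k <- m$end[j] - p$start[i] + 1L
    if (k >= 1L && k <= k_max) h[k] <- h[k] + p$copy[i] * m$copy[j]
  }
  h
}

# O(n^2) Dicer duplex pair enumeration (both 3' overhangs == overhang).
brute_dicer_pairs <- function(reads, size_range = c(20L, 24L),
                              overhang = 2L) {
  df <- as_df(reads)
  df$len <- df$end - df$start + 1L
  p <- df[df$strand == "+" & df$len >= size_range[1] &
            df$len <= size_range[2], ]
  m <- df[df$strand == "-" & df$len >= size_range[1] &
            df$len <= size_range[2], ]
  n <- 0L
  for (i in seq_len(nrow(p))) for (j in seq_len(nrow(m))) {
    if (p$chrom[i] != m$chrom[j]) next
    if (p$start[i] - m$start[j] == overhang &&
        p$end[i] - m$end[j] == overhang) n <- n + 1L
  }
  n
}

# O(n^2) phasing distance histogram (strand-aware, optional 1U filter).
brute_phasing_hist <- function(reads, d_max = 9L, require_1U = TRUE) {
  df <- as_df(reads)
  h <- stats::setNames(numeric(d_max), seq_len(d_max))
  for (i in seq_len(nrow(df))) for (j in seq_len(nrow(df))) {
    if (i == j || df$chrom[i] != df$chrom[j] ||
        df$strand[i] != df$strand[j]) next
    # i upstream, j downstream in the strand's 5'->3' direction
    d <- if (df$strand[i] == "+") df$start[j] - df$end[i]
         else df$start[i] - df$end[j]
    if (d < 1L || d > d_max) next
    if (require_1U && (is.na(df$first_nt[j]) || df$first_nt[j] != "U")) next
    h[d] <- h[d] + df$copy[i] * df$copy[j]
  }
  h
}

# Per-base coverage scan -> maximal islands with coverage >= min_depth.
brute_islands <- function(reads, seqlens, min_depth = 1L) {
  df <- as_df(reads)
  out <- NULL
  for (chr in names(seqlens)) {
    cov <- numeric(seqlens[[chr]])
    sub <- df[df$chrom == chr, ]
    for (i in seq_len(nrow(sub))) {
      idx <- sub$start[i]:sub$end[i]
      cov[idx] <- cov[idx] + sub$copy[i]
    }
    on <- cov >= min_depth
    r <- rle(on)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    if (any(keep)) {
      out <- rbind(out, data.frame(chrom = chr, start = starts[keep],
                                   end = ends[keep]))
    }
  }
  out
}

# Median-of-ratios size factors recomputed straight from the definition.
brute_size_factors <- function(m) {
  geo <- apply(m, 1L, function(r) exp(mean(log(r))))
  use <- apply(m, 1L, function(r) all(r > 0))
  apply(m, 2L, function(col) stats::median((col / geo)[use]))
}

# A small simulated bundle shared across tests (fixed seed).
std_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_library(sim_config(seed = 101L))
    }
    cache
  }
})

# Map annotated loci onto truth rows by reciprocal overlap >= `frac`.
match_truth <- function(loci, truth, frac = 0.5) {
  tr <- GenomicRanges::GRanges(truth$chrom,
                               IRanges::IRanges(truth$start, truth$end))
  hits <- GenomicRanges::findOverlaps(loci, tr, ignore.strand = TRUE)
  ov <- BiocGenerics::width(GenomicRanges::pintersect(
    loci[S4Vectors::queryHits(hits)], tr[S4Vectors::subjectHits(hits)],
    ignore.strand = TRUE))
  ok <- ov >= frac * BiocGenerics::width(loci)[S4Vectors::queryHits(hits)] &
    ov >= frac * BiocGenerics::width(tr)[S4Vectors::subjectHits(hits)]
  data.frame(locus = S4Vectors::queryHits(hits)[ok],
             truth = S4Vectors::subjectHits(hits)[ok])
}

# Shuffle read positions uniformly within a window, keeping lengths/strands.
shuffle_positions <- function(reads, region_start, region_end) {
  len <- BiocGenerics::width(reads)
  s <- vapply(len, function(l) {
    sample(seq.int(region_start, region_end - l + 1L), 1L)
  }, integer(1))
  make_reads(as.character(GenomicRanges::seqnames(reads)), s, s + len - 1L,
             as.character(BiocGenerics::strand(reads)),
             first_nt = S4Vectors::mcols(reads)$first_nt,
             copy = S4Vectors::mcols(reads)$copy)
}
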