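#' Per-locus read-size matrix
#'
#' One row per locus, one column per read length; cell values are
#' copy-weighted read counts. Reads are assigned to loci by 5'-end
#' containment, the same rule as locus counting, so row sums equal locus
#' counts restricted to the length window.
#'
#' @param loci `GRanges` of loci with a `locus_id` column.
#' @param library An [srna_library].
#' @param len_range Length window (default 15-35 nt).
#' @return Numeric matrix, rownames = locus ids, colnames = lengths.
#' @export
locus_size_matrix <- function(loci, library, len_range = c(15L, 35L)) {
  stopifnot(inherits(library, "srna_library"))
  lens <- seq.int(len_range[1], len_range[2])
  m <- matrix(0, nrow = length(loci), ncol = length(lens),
              dimnames = list(mcols(loci)$locus_id, lens))
  hits <- findOverlaps(five_prime_points(library$reads), loci,
                       ignore.strand = TRUE)
  if (length(hits) > 0L) {
    w <- width(library$reads)[queryHits(hits)]
    keep <- w >= len_range[1] & w <= len_range[2]
    df <- data.frame(row = subjectHits(hits)[keep], len = w[keep],
                     copy = read_copy(library$reads)[queryHits(hits)[keep]])
    if (nrow(df) > 0L) {
      agg <- tapply(df$copy,
                    list(factor(df$row, levels = seq_along(loci)),
                         factor(df$len, levels = lens)), sum)
      agg[is.na(agg)] <- 0
      m[, ] <- agg
    }
  }
  m
}

#' Row-wise z normalization
#'
#' Standardizes each row to mean 0 and sample sd 1, the "row normalized"
#' scaling used for size-distribution heatmaps. Constant rows cannot be
#' standardized and become all-zero rows, flagged in the
#' `"degenerate_rows"` attribute.
#'
#' @param m Numeric matrix (loci x lengths).
#' @return Matrix of the same shape with attribute `degenerate_rows`
#'   (logical vector).
#' @export
row_zscore <- function(m) {
  mu <- rowMeans(m)
  s <- apply(m, 1L, sd)
  degenerate <- is.na(s) | s == 0
  z <- (m - mu) / ifelse(degenerate, 1, s)
  z[degenerate, ] <- 0
  attr(z, "degenerate_rows") <- degenerate
  z
}

#' Hierarchical row order of a size matrix
#'
#' Hierarchical clustering (Euclidean distance, average linkage) of the
#' z-normalized rows, as used to order heatmap rows. Deterministic for a
#' given input.
#'
#' @param m Numeric matrix; rows are clustered.
#' @param method Linkage (default `"average"`).
#' @return Integer leaf order (a permutation of row indices); single-row
#'   input returns the identity.
#' @export
cluster_rows <- function(m, method = "average") {
  if (nrow(m) < 2L) return(seq_len(nrow(m)))
  hclust(dist(m), method = method)$order
}

#' Per-locus signature scores
#'
#' Computes the Ping Pong and phasing z-scores and the 1U fraction for the
#' reads of each locus (assigned by 5'-end containment).
#'
#' @param loci `GRanges` of loci with a `locus_id` column.
#' @param library An [srna_library].
#' @param k_max,d_max,require_1U Passed to the signature functions.
#' @return A data.frame with columns `locus_id`, `pingpong_z`, `phasing_z`,
#'   `first_u_fraction`, `n_reads`.
#' @export
locus_signatures <- function(loci, library, k_max = 25L, d_max = 9L,
                             require_1U = TRUE) {
  stopifnot(inherits(library, "srna_library"))
  hits <- findOverlaps(five_prime_points(library$reads), loci,
                       ignore.strand = TRUE)
  idx <- split(queryHits(hits), subjectHits(hits))
  res <- lapply(seq_along(loci), function(i) {
    j <- idx[[as.character(i)]]
    if (is.null(j) || length(j) == 0L) {
      return(data.frame(pingpong_z = NA_real_, phasing_z = NA_real_,
                        first_u_fraction = NA_real_, n_reads = 0L))
    }
    r <- library$reads[j]
    data.frame(
      pingpong_z = pingpong_zscore(overlap_histogram(r, k_max)),
      phasing_z = phasing_zscore(phasing_histogram(r, d_max, require_1U)),
      first_u_fraction = first_nt_fraction(r),
      n_reads = length(r))
  })
  cbind(data.frame(locus_id = mcols(loci)$locus_id), do.call(rbind, res))
}

#' Classify loci by read-size profile
#'
#' Assigns each locus the class holding the majority of its (in-window) read
#' mass: `pirna_like` for 26-30 nt, `dicer_sized` for 18-24 nt,
#' `degradation_like` for sub-18-nt reads, otherwise `ambiguous`. In strict
#' mode a `pirna_like` call additionally requires a high Ping Pong z-score,
#' the rule used to select confident piRNA loci; loci failing it fall back
#' to `ambiguous`.
#'
#' @param size_matrix Raw count matrix from [locus_size_matrix()].
#' @param signatures Optional data.frame from [locus_signatures()] (needed
#'   for `strict = TRUE`), matched by `locus_id`.
#' @param pirna_range,dicer_range piRNA / Dicer size windows (nt).
#' @param deg_max Largest degradation-sized length (nt, default 17).
#' @param majority Majority-mass threshold (default 0.5).
#' @param strict Require `pingpong_z >= z_min` for `pirna_like` calls.
#' @param z_min Ping Pong z threshold for strict mode (default 1.96).
#' @return A data.frame: `locus_id`, `class` (factor with levels
#'   `pirna_like`, `dicer_sized`, `degradation_like`, `ambiguous`),
#'   `frac_pirna`, `frac_dicer`, `frac_deg`, and when signatures are given,
#'   `pingpong_z`, `phasing_z`.
#' @export
classify_loci <- function(size_matrix, signatures = NULL,
                          pirna_range = c(26L, 30L),
                          dicer_range = c(18L, 24L), deg_max = 17L,
                          majority = 0.5, strict = FALSE, z_min = 1.96) {
  lens <- as.integer(colnames(size_matrix))
  totals <- rowSums(size_matrix)
  if (any(totals == 0)) stop("empty locus row(s) cannot be classified")
  frac_in <- function(sel) rowSums(size_matrix[, sel, drop = FALSE]) / totals
  frac_pirna <- frac_in(lens >= pirna_range[1] & lens <= pirna_range[2])
  frac_dicer <- frac_in(lens >= dicer_range[1] & lens <= dicer_range[2])
  frac_deg <- frac_in(lens <= deg_max)
  cls <- rep("ambiguous", nrow(size_matrix))
  cls[frac_deg >= majority] <- "degradation_like"
  cls[frac_dicer >= majority] <- "dicer_sized"
  cls[frac_pirna >= majority] <- "pirna_like"
  out <- data.frame(
    locus_id = rownames(size_matrix),
    class = cls, frac_pirna = frac_pirna, frac_dicer = frac_dicer,
    frac_deg = frac_deg, row.names = NULL)
  if (!is.null(signatures)) {
    m <- match(out$locus_id, signatures$locus_id)
    out$pingpong_z <- signatures$pingpong_z[m]
    out$phasing_z <- signatures$phasing_z[m]
    if (strict) {
      fail <- out$class == "pirna_like" &
        (is.na(out$pingpong_z) | out$pingpong_z < z_min)
      out$class[fail] <- "ambiguous"
    }
  } else if (strict) {
    stop("strict classification needs locus signatures")
  }
  out$class <- factor(out$class, levels = c("pirna_like", "dicer_sized",
                                            "degradation_like", "ambiguous"))
  out
}
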