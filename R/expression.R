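#' Locus-by-sample count matrix
#'
#' Counts each sample's reads per locus with the same 5'-end containment
#' rule used throughout, so column sums equal each sample's assigned totals.
#' All libraries must be mapped against the same reference.
#'
#' @param loci `GRanges` of loci with a `locus_id` column.
#' @param libraries A named list of [srna_library] objects (names become
#'   column names; otherwise `sample_id`s are used).
#' @return Numeric matrix loci x samples with attribute `total_mapped`
#'   (per-column library totals, the RPM denominators).
#' @export
count_matrix <- function(loci, libraries) {
  stopifnot(length(libraries) >= 1L)
  ids <- names(libraries)
  if (is.null(ids)) ids <- vapply(libraries, `[[`, "", "sample_id")
  ref <- libraries[[1]]$seqlengths
  for (lib in libraries) {
    if (!identical(lib$seqlengths, ref)) {
      stop("libraries are mapped against different genomes")
    }
  }
  m <- vapply(libraries, function(lib) region_counts(loci, lib),
              numeric(length(loci)))
  m <- matrix(m, nrow = length(loci),
              dimnames = list(mcols(loci)$locus_id, ids))
  attr(m, "total_mapped") <- vapply(libraries, `[[`, numeric(1),
                                    "total_mapped")
  m
}

#' Normalize a count matrix
#'
#' `rpm` scales each column to reads per million of its library total (the
#' `total_mapped` attribute when present, otherwise the column sum).
#' `median_of_ratios` computes per-sample size factors as the median across
#' loci of the ratio of the count to the row geometric mean, skipping rows
#' containing any zero — the scaling DESeq-style workflows use — and divides
#' each column by its factor.
#'
#' @param m Count matrix from [count_matrix()].
#' @param method `"median_of_ratios"` (default) or `"rpm"`.
#' @param drop_zero_rows Drop loci with zero counts in all samples first
#'   (default TRUE).
#' @return Normalized matrix with attribute `size_factors` (for
#'   `median_of_ratios`) or `total_mapped` (for `rpm`).
#' @export
normalize_counts <- function(m, method = c("median_of_ratios", "rpm"),
                             drop_zero_rows = TRUE) {
  method <- match.arg(method)
  totals <- attr(m, "total_mapped")
  if (drop_zero_rows) m <- m[rowSums(m) > 0, , drop = FALSE]
  if (method == "rpm") {
    if (is.null(totals)) totals <- colSums(m)
    out <- sweep(m, 2L, totals / 1e6, "/")
    attr(out, "total_mapped") <- totals
    return(out)
  }
  pos <- rowSums(m == 0) == 0
  if (!any(pos)) {
    warning("every locus has a zero count; falling back to rpm scaling")
    return(normalize_counts(m, "rpm", drop_zero_rows = FALSE))
  }
  geo <- exp(rowMeans(log(m[pos, , drop = FALSE])))
  sf <- apply(m[pos, , drop = FALSE], 2L,
              function(col) median(col / geo))
  out <- sweep(m, 2L, sf, "/")
  attr(out, "size_factors") <- sf
  out
}

#' Per-locus log2 fold change between sample groups
#'
#' @param norm Normalized matrix from [normalize_counts()].
#' @param group_a,group_b Column names or indices of the two groups
#'   (baseline a, comparison b); must be disjoint and non-empty.
#' @param pseudocount Added to both group means before the ratio
#'   (default 1).
#' @return Named numeric vector: `log2((mean_b + pc) / (mean_a + pc))` per
#'   locus.
#' @export
log2fc <- function(norm, group_a, group_b, pseudocount = 1) {
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop("both groups must be non-empty")
  }
  a <- norm[, group_a, drop = FALSE]
  b <- norm[, group_b, drop = FALSE]
  if (ncol(a) + ncol(b) > ncol(norm)) stop("groups must be disjoint")
  log2((rowMeans(b) + pseudocount) / (rowMeans(a) + pseudocount))
}

#' PCA of samples on locus expression
#'
#' Principal components of the samples (observations) over loci (features),
#' computed on `log2(normalized + 1)` with per-feature centering.
#'
#' @param norm Normalized matrix (loci x samples).
#' @return A list of class `srna_pca`: `coordinates` (samples x PCs),
#'   `explained_variance` (fractions, decreasing), `degenerate` (TRUE when
#'   all samples coincide and no variance exists to decompose).
#' @export
srna_pca <- function(norm) {
  if (ncol(norm) < 2L) stop("PCA needs at least 2 samples")
  x <- t(log2(norm + 1))
  p <- prcomp(x, center = TRUE, scale. = FALSE)
  tot <- sum(p$sdev^2)
  structure(list(
    coordinates = p$x,
    explained_variance = if (tot > 0) p$sdev^2 / tot else
      rep(NA_real_, length(p$sdev)),
    degenerate = tot == 0), class = "srna_pca")
}

#' @export
print.srna_pca <- function(x, ...) {
  cat("srna_pca:", nrow(x$coordinates), "samples\n")
  if (x$degenerate) {
    cat("  degenerate: all samples identical\n")
  } else {
    ev <- round(100 * x$explained_variance[seq_len(min(3,
      length(x$explained_variance)))], 1)
    cat("  explained variance (%):", paste(ev, collapse = ", "), "...\n")
  }
  invisible(x)
}
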