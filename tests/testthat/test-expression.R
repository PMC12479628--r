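two_sample_sim <- function(seed_a = 501L, seed_b = 502L) {
  # two samples over the same genome/loci: simulate once (with dispersed
  # per-locus depths), then thin reads for the second sample
  sim <- simulate_library(sim_config(seed = seed_a, noise_reads = 0L,
                                     depth_dispersion = 0.6))
  lib_a <- sim$library
  set.seed(seed_b)
  keep <- runif(length(lib_a$reads)) < 0.8
  lib_b <- srna_library(lib_a$reads[keep], lib_a$seqlengths, "sampleB")
  list(sim = sim, libraries = list(sampleA = lib_a, sampleB = lib_b))
}

test_that("count matrix assigns reads per sample with conserved columns", {
  ts <- two_sample_sim()
  loci <- annotate_loci(ts$libraries$sampleA, min_rpm = 5000)
  cm <- count_matrix(loci, ts$libraries)
  expect_equal(dim(cm), c(length(loci), 2L))
  # column sums equal per-sample totals assigned to loci
  for (s in 1:2) {
    lib <- ts$libraries[[s]]
    hits <- GenomicRanges::findOverlaps(
      srnasig:::five_prime_points(lib$reads), loci, ignore.strand = TRUE)
    expect_equal(sum(cm[, s]),
                 sum(S4Vectors::mcols(lib$reads)$copy[
                   S4Vectors::queryHits(hits)]))
  }
  # thinned replicate stays strongly correlated
  expect_gte(cor(cm[, 1], cm[, 2], method = "spearman"), 0.9)
  # mismatched genomes rejected
  other <- ts$libraries$sampleA
  other$seqlengths <- c(zzz = 1000L)
  expect_error(count_matrix(loci, list(ts$libraries$sampleA, other)),
               "different genomes")
})

test_that("median-of-ratios size factors match brute-force recomputation", {
  for (seed in 1:40) {
    set.seed(seed)
    n_loci <- sample(5:20, 1)
    m <- matrix(rpois(n_loci * 4, lambda = 50) + 1, nrow = n_loci,
                dimnames = list(paste0("L", seq_len(n_loci)),
                                paste0("s", 1:4)))
    norm <- normalize_counts(m)
    expect_equal(unname(attr(norm, "size_factors")),
                 unname(brute_size_factors(m)), info = paste("seed", seed))
  }
})

test_that("normalization contracts: rpm consistency, doubling, zero rows", {
  m <- matrix(c(10, 20, 30, 40), ncol = 1,
              dimnames = list(paste0("L", 1:4), "s1"))
  attr(m, "total_mapped") <- c(s1 = 2e6)
  expect_equal(unname(normalize_counts(m, "rpm")[, 1]),
               rpm(c(10, 20, 30, 40), 2e6))
  # exact doubling -> size factor ratio 2, equal normalized columns
  m2 <- cbind(a = c(10, 25, 40), b = c(20, 50, 80))
  rownames(m2) <- paste0("L", 1:3)
  norm <- normalize_counts(m2)
  sf <- attr(norm, "size_factors")
  expect_equal(unname(sf["b"] / sf["a"]), 2)
  expect_equal(unname(norm[, "a"]), unname(norm[, "b"]))
  # all-zero rows dropped before normalization
  m3 <- cbind(a = c(0, 5, 3), b = c(0, 4, 2))
  rownames(m3) <- paste0("L", 1:3)
  expect_equal(nrow(normalize_counts(m3)), 2L)
  # when every locus has a zero the ratio median is undefined -> rpm fallback
  m4 <- cbind(a = c(0, 5, 3), b = c(2, 0, 0))
  rownames(m4) <- paste0("L", 1:3)
  expect_warning(norm4 <- normalize_counts(m4), "zero")
  expect_equal(nrow(norm4), 3L)
})

test_that("depth artifacts are removed by median-of-ratios normalization", {
  set.seed(77)
  m <- matrix(rpois(60, 40) + 1, nrow = 15,
              dimnames = list(paste0("L", 1:15), paste0("s", 1:4)))
  # a sample sequenced 10x deeper than an otherwise identical one
  # normalizes to the same column exactly
  m10 <- cbind(m, s5 = m[, 1] * 10)
  norm <- normalize_counts(m10)
  expect_equal(unname(norm[, "s1"]), unname(norm[, "s5"]),
               tolerance = 1e-12)
  sf <- attr(norm, "size_factors")
  expect_equal(unname(sf["s5"] / sf["s1"]), 10)
  # scaling one library rescales every normalized value by one global
  # constant: between-sample ratios are depth-invariant
  norm1 <- normalize_counts(m)
  m2 <- m
  m2[, 2] <- m[, 2] * 10
  norm2 <- normalize_counts(m2)
  ratio <- norm2 / norm1
  expect_lt(diff(range(ratio)), 1e-9)
})

test_that("size factors agree with DESeq2 on odd-sized usable row sets", {
  skip_if_not_installed("DESeq2")
  set.seed(123)
  m <- matrix(rpois(55 * 5, 80) + 1, nrow = 55,
              dimnames = list(paste0("L", 1:55), paste0("s", 1:5)))
  sf <- attr(normalize_counts(m), "size_factors")
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(sf), unname(ref), tolerance = 1e-10)
})

test_that("log2 fold changes follow the pseudocount formula", {
  norm <- cbind(a1 = c(10, 0, 5), a2 = c(10, 0, 7),
                b1 = c(10, 0, 22), b2 = c(10, 0, 26))
  rownames(norm) <- paste0("L", 1:3)
  fc <- log2fc(norm, c("a1", "a2"), c("b1", "b2"))
  expect_equal(unname(fc[1]), 0)
  expect_equal(unname(fc[2]), 0)
  expect_equal(unname(fc[3]), log2(25 / 7))
  expect_error(log2fc(norm, character(), "b1"), "non-empty")
})

test_that("a simulated 4x shift is recovered within simulation error", {
  set.seed(88)
  n <- 30
  base <- rpois(n, 400) + 50
  shift <- rep(1, n)
  shift[5] <- 4
  m <- cbind(a1 = rpois(n, base), a2 = rpois(n, base),
             b1 = rpois(n, base * shift), b2 = rpois(n, base * shift))
  rownames(m) <- paste0("L", seq_len(n))
  norm <- normalize_counts(m)
  fc <- log2fc(norm, c("a1", "a2"), c("b1", "b2"))
  expect_equal(unname(fc[5]), 2, tolerance = 0.15)
  expect_lt(max(abs(fc[-5])), 0.5)
})

test_that("PCA separates two expression profiles and obeys variance laws", {
  set.seed(99)
  n <- 40
  prof1 <- rpois(n, 200) + 20
  prof2 <- prof1
  idx <- sample(n, 12)
  prof2[idx] <- prof2[idx] * sample(c(0.2, 5), 12, replace = TRUE)
  m <- sapply(1:8, function(i) rpois(n, if (i <= 4) prof1 else prof2))
  dimnames(m) <- list(paste0("L", 1:n), paste0("s", 1:8))
  p <- srna_pca(normalize_counts(m))
  km <- kmeans(p$coordinates[, 1:2], centers = 2, nstart = 10)
  expect_equal(length(unique(km$cluster[1:4])), 1L)
  expect_equal(length(unique(km$cluster[5:8])), 1L)
  expect_false(km$cluster[1] == km$cluster[5])
  ev <- p$explained_variance
  expect_lte(sum(ev), 1 + 1e-9)
  expect_true(all(diff(ev) <= 1e-9))
  # identical samples -> degenerate flag
  ident <- cbind(a = c(5, 10, 2), b = c(5, 10, 2))
  rownames(ident) <- paste0("L", 1:3)
  p2 <- srna_pca(ident)
  expect_true(p2$degenerate)
  expect_equal(unname(p2$coordinates[1, ]), unname(p2$coordinates[2, ]))
  expect_error(srna_pca(ident[, 1, drop = FALSE]), "2 samples")
})
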