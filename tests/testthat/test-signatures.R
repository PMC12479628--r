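test_that("overlap histogram matches the definition on worked examples", {
  # 0-based [2000,2028) x [1982,2010): 1-based [2001,2028] x [1983,2010]
  r <- make_reads("chrA", c(2001L, 1983L), c(2028L, 2010L), c("+", "-"))
  h <- overlap_histogram(r)
  expect_equal(unname(h[10]), 1)
  expect_equal(sum(h), 1)
  # 0-based [100,122) x [78,110): k = 110 - 100 = 10
  r <- make_reads("chrA", c(101L, 79L), c(122L, 110L), c("+", "-"))
  expect_equal(unname(overlap_histogram(r)[10]), 1)
  expect_error(overlap_histogram(r, k_max = 0L), "k_max")
})

test_that("overlap histogram equals brute-force all-pairs recount", {
  for (seed in 1:40) {
    set.seed(seed)
    reads <- random_reads(sample(20:120, 1))
    expect_equal(overlap_histogram(reads), brute_overlap_hist(reads),
                 info = paste("seed", seed))
  }
})

test_that("ping-pong z-score follows the focal-bin contract", {
  h <- setNames(numeric(25), 1:25)
  h[10] <- 100
  expect_true(is.na(pingpong_zscore(h)))      # flat zero background
  h_u <- setNames(rep(4, 25), 1:25)
  expect_true(is.na(pingpong_zscore(h_u)))    # uniform background
  set.seed(42)
  h2 <- setNames(rpois(25, 5), 1:25)
  h2[10] <- 50
  bg <- h2[-10]
  expect_equal(pingpong_zscore(h2), (h2[[10]] - mean(bg)) / sd(bg))
  expect_error(pingpong_zscore(h2[1:9]), "bin 10")
})

test_that("Dicer pair detection applies both-end overhang geometry", {
  # 0-based: P=[1000,1022), M=[998,1020) -> 1-based [1001,1022] [999,1020]
  r <- make_reads("chrA", c(1001L, 999L), c(1022L, 1020L), c("+", "-"))
  expect_equal(nrow(find_dicer_pairs(r)), 1L)
  # 1-nt overhangs are not Dicer pairs
  r2 <- make_reads("chrA", c(1001L, 1000L), c(1022L, 1021L), c("+", "-"))
  expect_equal(nrow(find_dicer_pairs(r2)), 0L)
  expect_equal(nrow(find_dicer_pairs(r2, ends = "either")), 0L)
  # asymmetric mode accepts a single matching overhang
  r3 <- make_reads("chrA", c(1001L, 999L), c(1022L, 1021L), c("+", "-"))
  expect_equal(nrow(find_dicer_pairs(r3)), 0L)
  expect_equal(nrow(find_dicer_pairs(r3, ends = "either")), 1L)
  # size screen: 26-nt reads are outside the 20-24 window
  r4 <- make_reads("chrA", c(1001L, 999L), c(1026L, 1024L), c("+", "-"))
  expect_equal(nrow(find_dicer_pairs(r4)), 0L)
  expect_error(find_dicer_pairs(r, size_range = c(24L, 20L)), "inverted")
})

test_that("Dicer pair counts equal brute-force enumeration", {
  for (seed in 1:40) {
    set.seed(seed)
    reads <- random_reads(sample(20:120, 1), len_range = c(18L, 26L))
    expect_equal(nrow(find_dicer_pairs(reads)), brute_dicer_pairs(reads),
                 info = paste("seed", seed))
  }
})

test_that("percent_dicer_pairs separates duplex-rich from piRNA-only input", {
  r <- make_reads("chrA", c(1001L, 999L, 2001L, 1999L, 3001L),
                  c(1022L, 1020L, 2022L, 2020L, 3028L),
                  c("+", "-", "+", "-", "+"), seqlens = c(chrA = 5000L))
  lib <- srna_library(r)
  pct <- percent_dicer_pairs(lib)
  expect_equal(as.numeric(pct), 100 * 2 / 5)
  expect_equal(attr(pct, "n_pairs"), 2L)

  sirna_rich <- simulate_library(sim_config(
    seed = 21L, n_loci_per_class = c(sirna = 6L, pingpong = 7L, phased = 7L),
    noise_reads = 0L))
  pirna_only <- simulate_library(sim_config(
    seed = 22L, n_loci_per_class = c(pingpong = 10L, phased = 10L),
    noise_reads = 0L))
  a <- as.numeric(percent_dicer_pairs(sirna_rich$library))
  b <- as.numeric(percent_dicer_pairs(pirna_only$library))
  expect_gt(a, 1)
  expect_gte(a, 5 * max(b, 1e-9))
})

test_that("phasing histogram applies strand-aware distances and 1U filter", {
  # plus strand, adjacent, downstream starts with U
  r <- make_reads("chrA", c(5001L, 5028L), c(5027L, 5055L), c("+", "+"),
                  first_nt = c("A", "U"))
  expect_equal(unname(phasing_histogram(r)[1]), 1)
  # same geometry, downstream not 1U -> filtered unless disabled
  r2 <- make_reads("chrA", c(5001L, 5028L), c(5027L, 5055L), c("+", "+"),
                   first_nt = c("A", "G"))
  expect_equal(sum(phasing_histogram(r2)), 0)
  expect_equal(unname(phasing_histogram(r2, require_1U = FALSE)[1]), 1)
  # minus-strand mirror: upstream is the rightmost read
  r3 <- make_reads("chrA", c(5028L, 5001L), c(5055L, 5027L), c("-", "-"),
                   first_nt = c("A", "U"))
  expect_equal(unname(phasing_histogram(r3)[1]), 1)
})

test_that("phasing histogram equals brute-force recount", {
  for (seed in 1:40) {
    set.seed(seed)
    reads <- random_reads(sample(20:120, 1),
                          seqlens = c(chrA = 2000L, chrB = 1500L))
    expect_equal(phasing_histogram(reads), brute_phasing_hist(reads),
                 info = paste("seed", seed))
    expect_equal(phasing_histogram(reads, require_1U = FALSE),
                 brute_phasing_hist(reads, require_1U = FALSE),
                 info = paste("seed", seed, "no filter"))
  }
})

test_that("phasing z-score mirrors the focal-bin contract on bin 1", {
  set.seed(7)
  h <- setNames(c(80, rpois(8, 4)), 1:9)
  bg <- h[-1]
  expect_equal(phasing_zscore(h), (h[[1]] - mean(bg)) / sd(bg))
  expect_true(is.na(phasing_zscore(setNames(numeric(9), 1:9))))
  expect_true(is.na(phasing_zscore(setNames(rep(3, 9), 1:9))))
})

test_that("first_nt_fraction is copy-weighted and total", {
  r <- make_reads("chrA", 1:10 * 100L, 1:10 * 100L + 21L, "+",
                  first_nt = c(rep("U", 9), "G"))
  expect_equal(first_nt_fraction(r), 0.9)
  expect_equal(first_nt_fraction(r, "A"), 0)
  expect_error(first_nt_fraction(r[0]), "empty")
  S4Vectors::mcols(r)$copy <- c(rep(1L, 9), 11L)
  expect_equal(first_nt_fraction(r), 9 / 20)
})

test_that("histograms are invariant under reverse-complementing the library", {
  flip_reads <- function(reads, seqlens) {
    chrom <- as.character(GenomicRanges::seqnames(reads))
    L <- seqlens[chrom]
    make_reads(chrom, L - BiocGenerics::end(reads) + 1L,
               L - BiocGenerics::start(reads) + 1L,
               ifelse(as.character(BiocGenerics::strand(reads)) == "+",
                      "-", "+"),
               first_nt = S4Vectors::mcols(reads)$first_nt,
               copy = S4Vectors::mcols(reads)$copy)
  }
  seqlens <- c(chrA = 5000L, chrB = 3000L)
  for (seed in 1:10) {
    set.seed(seed)
    reads <- random_reads(80, seqlens = seqlens)
    flipped <- flip_reads(reads, seqlens)
    expect_equal(overlap_histogram(reads), overlap_histogram(flipped))
    expect_equal(phasing_histogram(reads), phasing_histogram(flipped))
    expect_equal(nrow(find_dicer_pairs(reads, size_range = c(15L, 32L))),
                 nrow(find_dicer_pairs(flipped, size_range = c(15L, 32L))))
  }
})

test_that("histogram weighting collapses consistently with copy numbers", {
  set.seed(33)
  reads <- random_reads(60)
  S4Vectors::mcols(reads)$copy <- 1L
  dup <- rep(seq_along(reads), sample(1:3, length(reads), replace = TRUE))
  expanded <- reads[dup]
  collapsed <- reads
  S4Vectors::mcols(collapsed)$copy <- as.integer(tabulate(dup,
                                                          length(reads)))
  expect_equal(overlap_histogram(expanded), overlap_histogram(collapsed))
  expect_equal(phasing_histogram(expanded), phasing_histogram(collapsed))
})
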