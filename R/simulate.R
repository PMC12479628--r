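#' Simulation configuration
#'
#' Parameters of the synthetic small-RNA alignment generator. The defaults
#' describe a compact but realistic survey library: a few dozen loci of each
#' biogenesis class on a small random genome, ~50 alignments per locus,
#' piRNA-sized reads of 26-30 nt with a strong (90%) 1U bias, Dicer-sized
#' reads of 20-24 nt, and a degradation background below 18 nt.
#'
#' @param seed Integer seed; the generator is fully deterministic given
#'   `seed` and the remaining parameters.
#' @param n_chromosomes,chrom_length Genome shape (uniform random A/C/G/T).
#' @param n_loci_per_class Named counts for classes `mirna`, `sirna`,
#'   `pingpong`, `phased`, `degradation`.
#' @param reads_per_locus Mean alignments emitted per locus.
#' @param depth_dispersion Lognormal sd (log scale) of per-locus depth around
#'   `reads_per_locus`; 0 (default) gives every locus the same depth.
#' @param pirna_len_range,dicer_len_range,deg_len_range Read-length ranges
#'   (nt) for piRNA-, Dicer- and degradation-sized reads.
#' @param u1_bias Probability that a biased piRNA read starts with U.
#' @param pingpong_fraction Fraction of a Ping Pong locus' reads placed as
#'   exact 10-nt-overlap partner pairs (the rest are lone piRNAs).
#' @param adjacent_fraction Fraction of phased-train junctions at the
#'   head-to-tail distance of 1 nt (the rest fall at 2-9 nt).
#' @param noise_reads Number of uniformly placed random-length background
#'   reads.
#' @param locus_spacing Minimum gap enforced between simulated loci (bp);
#'   generous spacing keeps merge-gap sweeps predictable.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chrom_length = 100000L,
                       n_loci_per_class = c(mirna = 5L, sirna = 5L,
                                            pingpong = 5L, phased = 5L,
                                            degradation = 5L),
                       reads_per_locus = 50L,
                       depth_dispersion = 0,
                       pirna_len_range = c(26L, 30L),
                       dicer_len_range = c(20L, 24L),
                       deg_len_range = c(12L, 17L),
                       u1_bias = 0.9,
                       pingpong_fraction = 0.9,
                       adjacent_fraction = 0.9,
                       noise_reads = 100L,
                       locus_spacing = 2000L) {
  classes <- c("mirna", "sirna", "pingpong", "phased", "degradation")
  n <- setNames(integer(5L), classes)
  n[names(n_loci_per_class)] <- as.integer(n_loci_per_class)
  cfg <- list(seed = as.integer(seed),
              n_chromosomes = as.integer(n_chromosomes),
              chrom_length = as.integer(chrom_length),
              n_loci_per_class = n,
              reads_per_locus = as.integer(reads_per_locus),
              depth_dispersion = depth_dispersion,
              pirna_len_range = as.integer(pirna_len_range),
              dicer_len_range = as.integer(dicer_len_range),
              deg_len_range = as.integer(deg_len_range),
              u1_bias = u1_bias,
              pingpong_fraction = pingpong_fraction,
              adjacent_fraction = adjacent_fraction,
              noise_reads = as.integer(noise_reads),
              locus_spacing = as.integer(locus_spacing))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_chromosomes < 1L) stop("n_chromosomes must be >= 1")
  if (cfg$chrom_length < 10000L) stop("chrom_length must be >= 10000")
  if (any(cfg$n_loci_per_class < 0L) || cfg$reads_per_locus < 0L ||
      cfg$noise_reads < 0L) {
    stop("counts must be >= 0")
  }
  if (is.na(cfg$depth_dispersion) || cfg$depth_dispersion < 0) {
    stop("depth_dispersion must be >= 0")
  }
  for (r in list(cfg$pirna_len_range, cfg$dicer_len_range,
                 cfg$deg_len_range)) {
    if (length(r) != 2L || r[1] > r[2] || r[1] < 10L || r[2] > 40L) {
      stop("length ranges must lie within [10, 40] and be non-inverted")
    }
  }
  for (f in c(cfg$u1_bias, cfg$pingpong_fraction, cfg$adjacent_fraction)) {
    if (is.na(f) || f < 0 || f > 1) stop("fractions must lie in [0, 1]")
  }
  invisible(cfg)
}

#' Simulate a random genome
#'
#' @param config A [sim_config()]. Seeds the RNG with `config$seed`.
#' @return A [Biostrings::DNAStringSet] of `n_chromosomes` uniform random
#'   sequences named `chr1`, `chr2`, ...
#' @export
simulate_genome <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  seqs <- vapply(seq_len(config$n_chromosomes), function(i) {
    paste(sample(c("A", "C", "G", "T"), config$chrom_length, replace = TRUE),
          collapse = "")
  }, character(1))
  genome <- DNAStringSet(seqs)
  names(genome) <- paste0("chr", seq_len(config$n_chromosomes))
  genome
}

# Helper: build a read GRanges from parallel vectors, with the `bias` column
# recording a 5'-base constraint to realize later against the genome:
# NA (leave genome base alone), "U" (force U) or "V" (force non-U).
sim_reads <- function(chrom, start, end, strand, bias = NA_character_) {
  gr <- GRanges(chrom, IRanges(start, end), strand = strand)
  mcols(gr)$copy <- rep_len(1L, length(gr))
  mcols(gr)$bias <- rep_len(bias, length(gr))
  gr
}

rand_len <- function(n, range) {
  vals <- seq.int(range[1], range[2])
  if (length(vals) == 1L) rep(vals, n) else sample(vals, n, replace = TRUE)
}

draw_bias <- function(n, u1_bias) {
  ifelse(runif(n) < u1_bias, "U", "V")
}

#' Simulate one siRNA locus of tiled Dicer duplexes
#'
#' Emits `n_duplexes` plus/minus read pairs; every pair has the canonical
#' RNase III duplex geometry (2-nt 3' overhangs on both ends), and
#' consecutive duplexes tile the region head-to-tail. Uses the ambient RNG.
#'
#' @param chrom,start Chromosome name and 1-based start of the first plus
#'   read.
#' @param n_duplexes Number of duplexes.
#' @param len_range Duplex read length range (nt).
#' @return A `GRanges` of `2 * n_duplexes` reads.
#' @export
simulate_sirna_locus <- function(chrom, start, n_duplexes,
                                 len_range = c(20L, 24L)) {
  if (n_duplexes == 0L) return(sim_reads(character(), integer(), integer(),
                                         character()))
  lens <- rand_len(n_duplexes, len_range)
  pS <- start + c(0L, cumsum(lens))[seq_len(n_duplexes)]
  pE <- pS + lens - 1L
  plus <- sim_reads(chrom, pS, pE, "+")
  minus <- sim_reads(chrom, pS - 2L, pE - 2L, "-")
  c(plus, minus)
}

#' Simulate one miRNA-like locus
#'
#' One dominant ~22-nt mature duplex: `n_mature` identical plus-strand
#' alignments plus a low-abundance star strand completing the 2-nt 3'
#' overhang duplex geometry.
#'
#' @param chrom,start Placement of the mature read.
#' @param n_mature,n_star Alignment counts for mature and star reads.
#' @param len Mature/star length (nt).
#' @return A `GRanges` of reads.
#' @export
simulate_mirna_locus <- function(chrom, start, n_mature, n_star = NULL,
                                 len = 22L) {
  if (is.null(n_star)) n_star <- max(1L, round(0.1 * n_mature))
  if (n_mature == 0L) return(sim_reads(character(), integer(), integer(),
                                       character()))
  mature <- sim_reads(chrom, rep(start, n_mature),
                      rep(start + len - 1L, n_mature), "+")
  star <- sim_reads(chrom, rep(start - 2L, n_star),
                    rep(start + len - 3L, n_star), "-")
  c(mature, star)
}

#' Simulate one Ping Pong piRNA locus
#'
#' Places `n_pairs` opposite-strand piRNA pairs whose 5' ends overlap by
#' exactly 10 nt; initiator (plus-strand) reads carry the 1U bias. Optional
#' lone piRNAs (both strands, also 1U-biased) model reads without a detected
#' partner.
#'
#' @param chrom,start Chromosome and 1-based start of the locus window.
#' @param n_pairs Number of exact 10-nt-overlap pairs.
#' @param len_range piRNA length range (nt).
#' @param u1_bias Probability an initiator/lone read starts with U.
#' @param n_lone Number of unpaired piRNA reads.
#' @param span Width of the window pairs are scattered in (bp).
#' @return A `GRanges` of reads.
#' @export
simulate_pingpong_locus <- function(chrom, start, n_pairs,
                                    len_range = c(26L, 30L), u1_bias = 0.9,
                                    n_lone = 0L, span = 1000L) {
  out <- sim_reads(character(), integer(), integer(), character())
  margin <- len_range[2] + 12L
  if (n_pairs > 0L) {
    pS <- start + margin +
      sample.int(max(1L, span - 2L * margin), n_pairs, replace = TRUE) - 1L
    lenP <- rand_len(n_pairs, len_range)
    lenM <- rand_len(n_pairs, len_range)
    # 10-nt 5'-5' overlap: responder minus read ends 9 nt right of the
    # initiator's 5' base
    mE <- pS + 9L
    plus <- sim_reads(chrom, pS, pS + lenP - 1L, "+",
                      draw_bias(n_pairs, u1_bias))
    minus <- sim_reads(chrom, mE - lenM + 1L, mE, "-")
    out <- c(plus, minus)
  }
  if (n_lone > 0L) {
    s <- start + margin +
      sample.int(max(1L, span - 2L * margin), n_lone, replace = TRUE) - 1L
    len <- rand_len(n_lone, len_range)
    out <- c(out, sim_reads(chrom, s, s + len - 1L,
                            sample(c("+", "-"), n_lone, replace = TRUE),
                            draw_bias(n_lone, u1_bias)))
  }
  out
}

#' Simulate one phased (Zucchini) piRNA locus
#'
#' Emits a same-strand head-to-tail train: each read's 5' end follows the
#' previous read's 3' end at distance 1 (immediately adjacent) with
#' probability `adjacent_fraction`, otherwise at 2-9 nt. All reads carry the
#' 1U bias, as Zucchini cleavage at uridines dictates.
#'
#' @param chrom,start Chromosome and 1-based coordinate of the train's
#'   5'-most read start (leftmost for plus, determined rightwards for minus).
#' @param n_reads Number of reads in the train.
#' @param len_range piRNA length range (nt).
#' @param u1_bias Probability each read starts with U.
#' @param strand Train strand.
#' @param adjacent_fraction Probability of a distance-1 junction.
#' @return A `GRanges` of reads.
#' @export
simulate_phased_locus <- function(chrom, start, n_reads,
                                  len_range = c(26L, 30L), u1_bias = 0.9,
                                  strand = "+", adjacent_fraction = 0.9) {
  if (n_reads == 0L) return(sim_reads(character(), integer(), integer(),
                                      character()))
  lens <- rand_len(n_reads, len_range)
  gaps <- ifelse(runif(max(0L, n_reads - 1L)) < adjacent_fraction, 1L,
                 sample(2:9, max(0L, n_reads - 1L), replace = TRUE))
  # consecutive 5' starts sit gap nt after the previous 3' end; the same
  # coordinates serve both strands (on minus the roles upstream/downstream
  # read right-to-left but the inter-read distances are identical)
  s <- start + c(0L, cumsum(lens[-n_reads] + gaps - 1L))
  e <- s + lens - 1L
  sim_reads(chrom, s, e, strand, draw_bias(n_reads, u1_bias))
}

#' Simulate one degradation locus
#'
#' Sub-18-nt fragments scattered over a short window on both strands,
#' modelling RNA decay products that co-purify with small RNAs.
#'
#' @param chrom,start Placement of the window.
#' @param n_reads Number of fragments.
#' @param len_range Fragment length range (nt).
#' @param span Window width (bp).
#' @return A `GRanges` of reads.
#' @export
simulate_degradation_locus <- function(chrom, start, n_reads,
                                       len_range = c(12L, 17L),
                                       span = 300L) {
  if (n_reads == 0L) return(sim_reads(character(), integer(), integer(),
                                      character()))
  s <- start + sample.int(span, n_reads, replace = TRUE) - 1L
  len <- rand_len(n_reads, len_range)
  sim_reads(chrom, s, s + len - 1L,
            sample(c("+", "-"), n_reads, replace = TRUE))
}

# Place n loci of given widths uniformly on the genome with at least
# `spacing` bp between any two loci (and a margin from chromosome ends).
place_loci <- function(widths, seqlens, spacing, max_try = 200L) {
  n <- length(widths)
  chroms <- character(n); starts <- integer(n)
  placed <- vector("list", length(seqlens))
  names(placed) <- names(seqlens)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (t in seq_len(max_try)) {
      chr <- sample(names(seqlens), 1L, prob = as.numeric(seqlens))
      lim <- seqlens[[chr]] - widths[i] - 100L
      if (lim < 101L) next
      s <- sample.int(lim - 100L, 1L) + 100L
      prev <- placed[[chr]]
      if (is.null(prev) ||
          all(s > prev[, 2] + spacing | s + widths[i] - 1L <
                prev[, 1] - spacing)) {
        ok <- TRUE
        placed[[chr]] <- rbind(prev, c(s, s + widths[i] - 1L))
        chroms[i] <- chr; starts[i] <- s
        break
      }
    }
    if (!ok) stop("could not place locus ", i,
                  " without overlap; genome too crowded")
  }
  data.frame(chrom = chroms, start = starts, width = widths)
}

# Overwrite genome bases so that each read's observed 5' nucleotide matches
# its bias constraint ("U" -> U, "V" -> uniformly A/C/G).
apply_first_nt_bias <- function(genome, reads) {
  bias <- mcols(reads)$bias
  idx <- which(!is.na(bias))
  if (length(idx) == 0L) return(genome)
  minus <- as.character(strand(reads)) == "-"
  pos <- ifelse(minus, end(reads), start(reads))
  base <- ifelse(bias == "U", "T",
                 sample(c("A", "C", "G"), length(bias), replace = TRUE))
  # a minus-strand read sees the reverse complement of the genome base
  base[minus] <- chartr("ACGT", "TGCA", base[minus])
  for (chr in unique(as.character(seqnames(reads))[idx])) {
    j <- idx[as.character(seqnames(reads))[idx] == chr]
    # on the rare collision of two biased 5' ends at one base, last one wins
    j <- j[!duplicated(pos[j], fromLast = TRUE)]
    genome[[chr]] <- Biostrings::replaceLetterAt(
      genome[[chr]], pos[j], paste(base[j], collapse = ""))
  }
  genome
}

#' Simulate a complete small-RNA library with ground truth
#'
#' Composes a random genome, non-overlapping loci of the five biogenesis
#' classes, and uniform background noise into one library. Genome bases under
#' biased read 5' ends are overwritten so that the 1U bias is measurable from
#' the genome exactly as for real alignments; `first_nt` is then computed
#' from the final genome for every read, noise included.
#'
#' @param config A [sim_config()].
#' @return A list of class `srna_simulation` with elements `library` (an
#'   [srna_library]), `genome` ([Biostrings::DNAStringSet]) and `truth`
#'   (data.frame with one row per simulated locus: `locus_id`, `chrom`,
#'   `start`, `end` (1-based closed), `class`, `n_reads`, `u1_bias`).
#'   Each read in `library$reads` carries `truth_id` (`"noise"` for
#'   background reads).
#' @export
simulate_library <- function(config) {
  validate_sim_config(config)
  genome <- simulate_genome(config)   # also seeds the RNG with config$seed
  seqlens <- setNames(width(genome), names(genome))
  cls <- config$n_loci_per_class
  rpl <- config$reads_per_locus

  # expected genomic footprint per locus, used for collision-free placement
  specs <- do.call(rbind, lapply(names(cls), function(class) {
    if (cls[[class]] == 0L) return(NULL)
    data.frame(class = class, n = cls[[class]])
  }))
  if (!is.null(specs)) {
    specs <- specs[rep(seq_len(nrow(specs)), specs$n), "class", drop = FALSE]
    # per-locus depth: fixed, or lognormal around reads_per_locus
    specs$depth <- if (config$depth_dispersion > 0) {
      pmax(2L, as.integer(round(rpl * exp(stats::rnorm(
        nrow(specs), 0, config$depth_dispersion)))))
    } else rep(rpl, nrow(specs))
    specs$width <- as.integer(vapply(seq_len(nrow(specs)), function(i) {
      d <- specs$depth[i]
      switch(specs$class[i],
        mirna = 30,
        sirna = ceiling(d / 2) * config$dicer_len_range[2] + 10,
        pingpong = max(1000, 10 * d),
        phased = d * (config$pirna_len_range[2] + 8) + 10,
        degradation = 320)
    }, numeric(1)))
  }

  read_list <- list()
  truth <- NULL
  if (!is.null(specs)) {
    pos <- place_loci(specs$width, seqlens, config$locus_spacing)
    for (i in seq_len(nrow(specs))) {
      class <- specs$class[i]
      d <- specs$depth[i]
      chrom <- pos$chrom[i]; start <- pos$start[i]
      r <- switch(class,
        mirna = simulate_mirna_locus(chrom, start + 4L, n_mature = d),
        sirna = simulate_sirna_locus(chrom, start + 4L,
                                     n_duplexes = ceiling(d / 2),
                                     len_range = config$dicer_len_range),
        pingpong = {
          n_pairs <- floor(d * config$pingpong_fraction / 2)
          simulate_pingpong_locus(chrom, start, n_pairs,
                                  len_range = config$pirna_len_range,
                                  u1_bias = config$u1_bias,
                                  n_lone = max(0L, d - 2L * n_pairs),
                                  span = pos$width[i])
        },
        phased = simulate_phased_locus(chrom, start + 4L, n_reads = d,
                                       len_range = config$pirna_len_range,
                                       u1_bias = config$u1_bias,
                                       strand = sample(c("+", "-"), 1L),
                                       adjacent_fraction =
                                         config$adjacent_fraction),
        degradation = simulate_degradation_locus(chrom, start,
                                                 n_reads = d,
                                                 len_range =
                                                   config$deg_len_range))
      id <- sprintf("truth_%04d", i)
      mcols(r)$truth_id <- id
      read_list[[length(read_list) + 1L]] <- r
      truth <- rbind(truth, data.frame(
        locus_id = id, chrom = chrom,
        start = if (length(r)) min(start(r)) else start,
        end = if (length(r)) max(end(r)) else start,
        class = class, n_reads = length(r),
        u1_bias = if (class %in% c("pingpong", "phased"))
          config$u1_bias else NA_real_))
    }
  }

  if (config$noise_reads > 0L) {
    chr <- sample(names(seqlens), config$noise_reads, replace = TRUE,
                  prob = as.numeric(seqlens))
    len <- sample(15:35, config$noise_reads, replace = TRUE)
    s <- vapply(seq_len(config$noise_reads), function(i) {
      sample.int(seqlens[[chr[i]]] - len[i] - 1L, 1L)
    }, integer(1))
    noise <- sim_reads(chr, s, s + len - 1L,
                       sample(c("+", "-"), config$noise_reads,
                              replace = TRUE))
    mcols(noise)$truth_id <- "noise"
    read_list[[length(read_list) + 1L]] <- noise
  }

  read_list <- lapply(read_list, function(g) {
    seqlevels(g) <- names(seqlens)
    g
  })
  reads <- if (length(read_list)) do.call(c, read_list) else {
    r0 <- sim_reads(character(), integer(), integer(), character())
    mcols(r0)$truth_id <- character()
    seqlevels(r0) <- names(seqlens)
    r0
  }
  genome <- apply_first_nt_bias(genome, reads)
  mcols(reads)$bias <- NULL
  mcols(reads)$first_nt <- if (length(reads)) compute_first_nt(reads, genome)
                           else character()
  # collapse identical alignments into copy counts, as mapping of collapsed
  # (deduplicated) reads produces; total_mapped is unchanged by this
  key <- paste(as.character(seqnames(reads)), start(reads), end(reads),
               as.character(strand(reads)))
  if (anyDuplicated(key)) {
    tab <- tapply(mcols(reads)$copy, key, sum)
    reads <- reads[!duplicated(key)]
    mcols(reads)$copy <- as.integer(tab[paste(
      as.character(seqnames(reads)), start(reads), end(reads),
      as.character(strand(reads)))])
  }
  lib <- srna_library(reads, seqlens, sample_id = paste0("sim", config$seed),
                      meta = list(simulated = TRUE, seed = config$seed))
  if (is.null(truth)) {
    truth <- data.frame(locus_id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        class = character(), n_reads = integer(),
                        u1_bias = numeric())
  }
  structure(list(library = lib, genome = genome, truth = truth),
            class = "srna_simulation")
}

#' Write a simulation bundle to disk
#'
#' Writes `genome.fa`, `alignments.bed`, `alignments.sam`, `truth.tsv` and
#' the resolved configuration `config.json` into `dir`.
#'
#' @param sim An `srna_simulation` from [simulate_library()].
#' @param dir Output directory (created if needed).
#' @param config The [sim_config()] used (echoed to `config.json`); optional.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, config = NULL) {
  stopifnot(inherits(sim, "srna_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  write_bed(sim$library, file.path(dir, "alignments.bed"))
  write_sam(sim$library, sim$genome, file.path(dir, "alignments.sam"))
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(config)) {
    write_json(unclass(config), file.path(dir, "config.json"),
               auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(dir)
}
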