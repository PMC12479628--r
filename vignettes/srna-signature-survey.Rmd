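---
title: "Surveying small-RNA biogenesis signatures in read alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surveying small-RNA biogenesis signatures in read alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnasig)
```

## The problem

Animal small-RNA libraries mix three biogenesis pathways whose products
overlap in no single property but are separable by coordinate arithmetic on
genome alignments. Dicer cuts double-stranded precursors into 18–24-nt
duplexes whose strands carry 2-nt 3' overhangs at both ends; piRNAs are
longer (26–30 nt), Dicer-independent, and arise either through the Ping
Pong amplification loop (opposite-strand pairs with an exact 10-nt 5'–5'
overlap) or through Zucchini-mediated phasing (same-strand, head-to-tail
trains of reads starting with uridine). A survey of an unannotated genome's
small-RNA repertoire — which pathways are active, where the loci are, what
each locus produces, how locus expression varies across samples — can
therefore be phrased entirely as statistics over aligned read intervals.
`srnasig` implements that survey, together with a generator of synthetic
alignment libraries in which the ground truth of every locus is known.

This vignette records the models, parameter choices, numerical conventions
and known limitations. All coordinates are held internally as 1-based
closed `GRanges` intervals; BED input/output is converted at the boundary,
SAM input likewise, so no off-by-one reasoning leaks into the statistics.
Read 5' nucleotides are reported in RNA space (`U`, not `T`).

## Signature statistics

**Overlap histogram and Ping Pong z.** For a plus-strand read $P$ and a
physically overlapping minus-strand read $M$ on the same chromosome, the
5'–5' overlap is $k = \mathrm{end}(M) - \mathrm{start}(P) + 1$ (both reads'
5' ends included). Bin $k \in \{1,\dots,k_{\max}\}$ (default 25)
accumulates $\mathrm{copy}(P)\cdot\mathrm{copy}(M)$, so collapsed and
expanded representations of identical alignments give identical
histograms. The Ping Pong score is
$z_{10} = (h_{10} - \bar h_{B}) / s_{B}$ with background $B$ all bins
except 10 and $s_B$ the sample standard deviation. When $s_B = 0$ (empty or
uniform background) the score is undefined and returned as `NA` rather
than $\pm\infty$; callers treat `NA` as "no evidence".

**Dicer pairs and the percent-Dicer-pairs screen.** A Dicer pair is an
opposite-strand pair with both read lengths in 20–24 nt and
$\mathrm{start}(P)-\mathrm{start}(M) = \mathrm{end}(P)-\mathrm{end}(M) =
2$: the canonical RNase III duplex with 2-nt 3' overhangs at *both* ends.
An `ends = "either"` mode accepts a single matching overhang for
sensitivity analyses. The library-level screen is
$100 \times \#\text{pairs} / \#\text{alignments}$; each unordered pair
counts once, and the denominator is the length-screened total mapped count
(the pre-screen total is kept in library metadata and available via
`denominator = "prefilter"`). siRNA-producing species score percent-level
values; piRNA-only libraries score near zero, because 26–30-nt reads fail
the size window — the at-least-fivefold separation is exercised in the
acceptance suite.

**Phasing histogram and z.** For same-strand reads, upstream $U$ and
downstream $D$ in the strand's 5'→3' orientation, the distance is
$d = \mathrm{start}(D) - \mathrm{end}(U)$ on the plus strand and
$\mathrm{start}(U) - \mathrm{end}(D)$ on the minus strand, so $d = 1$
means immediately adjacent. Distances 1–9 are tracked; by default only
downstream reads with a 5' U contribute, matching the uridine specificity
of Zucchini cleavage (a `require_1U = FALSE` mode exists). The phasing
score is the bin-1 z against bins 2–9, same contract as $z_{10}$.

Both histogram z-scores use the all-other-bins background with sample
(n−1) standard deviation. The background window is a free choice — no
standard fixes it — and it is deliberately the same for both scores so a
single contract governs degenerate cases.

## Locus annotation

Loci are called from pooled-strand, copy-weighted per-base coverage:

1. **Islands**: maximal runs with coverage ≥ 1 (the most inclusive
   seeding; depth discrimination is delegated to the RPM filter).
2. **Merging**: islands with gaps ≤ 500 bp are fused, so clusters
   fragmented by mappability or sampling are not split into several
   candidate loci.
3. **Boundary trimming**: each merged region is trimmed to the span of its
   outermost coverage island supported by ≥ 2 assigned alignments
   (`min_island_reads = 2`; set 1 to disable). Without this step a single
   background alignment within the merge gap of a locus permanently
   widens it — merging precedes filtering, so no later threshold can undo
   the widening. A singleton flanking alignment is weak boundary
   evidence, and requiring two supporting reads at the boundary is the
   convention of piRNA cluster callers. Regions with no supported island
   (isolated singletons) are dropped.
4. **RPM filter**: reads are assigned to the region containing their 5'
   end — each read counted in exactly one locus, so locus counts are
   conserved — and regions below 1000 RPM (of the library's total mapped
   count) are discarded. A raw-count threshold is available via
   `min_count`.

`threshold_sweep()` recomputes the grid over merge gaps
{0, 5, 50, 500, 5000, 50000} bp and a decade grid of RPM thresholds,
reporting locus counts and genome coverage (locus bp over total genome bp,
Ns included), to make the choice of rule inspectable. Two monotonicity laws
hold by construction and are asserted over simulated libraries: locus
counts are non-increasing in the RPM threshold at fixed gap, and total
locus bp is non-decreasing in the gap at threshold 0. Whether the sweep's
depth axis is raw reads or RPM is ambiguous in general use; RPM is the
default here because the final rule is stated in RPM, and `min_count`
covers the raw reading.

## Per-locus profiles and classification

`locus_size_matrix()` gives per-locus read-length histograms (5'-end
assignment, window 15–35 nt by default); `row_zscore()` standardizes each
row to mean 0, sd 1 for heatmap display, mapping constant rows to zero and
flagging them rather than dividing by zero; `cluster_rows()` orders rows by
hierarchical clustering with Euclidean distance and average linkage —
unstated in common practice, so chosen once and recorded in output
metadata.

Classification uses majority read mass: piRNA-like if ≥ 50% of in-window
mass lies in 26–30 nt, else Dicer-sized if ≥ 50% in 18–24 nt, else
degradation-like if ≥ 50% below 18 nt, else ambiguous. miRNA and siRNA
loci are *not* separated — size alone cannot distinguish them, and hairpin
prediction is out of scope — so both fall in `dicer_sized`. The strict
mode additionally requires a Ping Pong z ≥ 1.96 for a piRNA-like call
(demoting failures to ambiguous); 1.96 is the two-sided 5% normal
quantile, a default for "high z-score" where no number is standard, and is
a visible parameter (`z_min`) in every report.

## Expression

`count_matrix()` builds locus × sample counts with the same 5'-end
assignment rule as annotation. Normalization is either RPM or
median-of-ratios: per-sample size factors are the median over loci of
$c_{ij}/g_i$, with $g_i$ the row geometric mean, computed over loci with
no zero count; if every locus contains a zero the method falls back to RPM
with a warning. The plain (not log-space) median is used, matching the
definition; the suite cross-checks the factors against DESeq2 on odd-sized
usable row sets where the two medians coincide. Median-of-ratios equalizes
depth between samples: an exact scalar multiple of a sample normalizes to
an identical column, and rescaling one library changes all normalized
values only by a single global constant. Dispersion estimation and
hypothesis testing are deliberately absent — those belong to dedicated DE
packages consuming this count matrix; `log2fc()` gives point estimates
with a pseudocount of 1 on group means, and `srna_pca()` decomposes
samples on `log2(normalized + 1)` with per-locus centering (the
pseudocount-log transform is a choice, made once).

## The synthetic generator

`simulate_library()` composes a uniform-random A/C/G/T genome (default two
chromosomes of 100 kb), non-overlapping loci of five classes, and uniform
background into one library with a per-locus truth table:

* **miRNA**: one dominant 22-nt duplex — a mature read at fixed
  coordinates plus ~10% star-strand reads in 2-nt-overhang geometry.
* **siRNA**: head-to-tail-tiled Dicer duplexes (20–24 nt, both overhangs
  exactly 2 nt).
* **Ping Pong**: opposite-strand piRNA pairs (26–30 nt) with exact 10-nt
  5' overlaps scattered in a ~1-kb window; 92–90% of reads are in pairs
  (`pingpong_fraction` 0.9), the rest lone piRNAs; initiator and lone
  reads take the 1U bias.
* **Phased**: a same-strand train whose junction distances are 1 with
  probability 0.9 and 2–9 otherwise; every read takes the 1U bias.
* **Degradation**: sub-18-nt fragments (12–17 nt) scattered over ~300 bp.
* **Noise**: 100 reads of 15–35 nt placed uniformly.

Defaults are five loci per class at ~50 alignments per locus, 1U bias 0.9,
and ≥ 2 kb between loci so the 500-bp merge gap never fuses distinct truth
loci. Optional `depth_dispersion` draws per-locus depth from a lognormal
around the mean, for expression analyses that need rank structure. The 1U
bias is realized by overwriting the genome base under each biased read's
5' end (complemented on the minus strand), so `first_nt` is computed from
the genome exactly as for real data; identical alignments are then
collapsed into `copy` counts, as mapping of deduplicated reads produces —
copy-weighted statistics are invariant to the collapse, and pair counts
refer to distinct coordinate pairs. One seed drives everything: the same
configuration yields byte-identical FASTA/BED/SAM/TSV outputs.

What the generator does *not* emulate: sequencing errors, adapters,
multi-mapping, chimeric or spliced alignments, transposon sequence
structure, realistic base composition, or the overdispersed abundance
distribution of real loci. Passing tests therefore demonstrate that the
statistics recover planted geometric signals through the full file-format
round trip — not that any particular biological library will show them.

## Problem sizes and numerical choices

The test and acceptance suites run at desk scale, chosen to keep the whole
suite within a few minutes while leaving sampling error far from the
asserted margins: oracle-equivalence checks use 100 random instances of
20–80 reads per operation against brute-force O(n²) recounts;
signature-recovery runs 40 Ping Pong loci (~55 pairs each) and 40 phased
loci (60 reads) with position-shuffled nulls; annotation recovery uses
five 25-locus libraries and twenty threshold sweeps; classification a
200-locus mixture; the 1U check a single 10,000-read phased locus.
Degenerate inputs are contracts, not accidents: empty read sets error in
`first_nt_fraction`, zero-variance backgrounds yield `NA` z-scores,
constant rows z-score to zero with a flag, identical samples flag PCA as
degenerate, and a zero total mapped count is a hard error for RPM.

## Limitations

Strand-pooled locus calling cannot separate interleaved antisense loci;
boundary trimming assumes background is sparse relative to locus coverage;
the percent-Dicer-pairs denominator choice (filtered vs pre-filter) shifts
absolute values between libraries processed with different length screens,
which is why both are reported; and classification thresholds (majority
0.5, z 1.96) are conventions, surfaced as parameters rather than baked in.
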