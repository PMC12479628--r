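# srnasig

Small-RNA biogenesis leaves arithmetic fingerprints in alignment
coordinates, and `srnasig` is an R package for finding them. Animal cells
make three classes of small silencing RNA, each with a distinct geometric
signature that survives into mapped sequencing reads:

* **Dicer products (miRNAs, endo-siRNAs, 18–24 nt).** RNase III enzymes cut
  double-stranded RNA into duplexes with 2-nt 3' overhangs: an
  opposite-strand read pair (P, M) is a *Dicer pair* when both reads are
  Dicer-sized and `start(P) − start(M) = end(P) − end(M) = 2`.
* **Ping Pong piRNAs (26–30 nt).** The piRNA amplification loop produces
  opposite-strand pairs whose 5' ends overlap by exactly 10 nt; enrichment
  is scored as the z-score of the 10-nt bin of the 5'–5' overlap histogram
  against all other bins.
* **Phased (Zucchini) piRNAs.** Endonucleolytic processing at uridines
  yields head-to-tail trains of 1U reads; enrichment is the z-score of
  distance 1 in the histogram of distances (1–9 nt) from a read's 3' end to
  the next 1U read's 5' end on the same strand.

Around these statistics the package implements a complete small-RNA survey:
the *percent-Dicer-pairs* screen (Dicer pairs divided by total library
alignments ×100, a one-number test for an active siRNA pathway),
annotation of small-RNA-expressing loci from read coverage (island
detection, gap merging, boundary trimming, RPM filtering, and a
merge-gap × RPM threshold sweep for choosing the rule), per-locus
read-size profiles with row-z heatmap scaling, hierarchical ordering and
class assignment (piRNA-like / Dicer-sized / degradation-like), and
locus × sample expression matrices with RPM or median-of-ratios
normalization, log2 fold changes and sample PCA.

Because these analyses are usually validated only by eye, `srnasig` ships a
synthetic alignment generator (`simulate_library()`) that plants each
signature in a random genome with per-locus ground-truth labels — every
stage of the pipeline is tested against brute-force oracles and against
what the generator planted.

## Worked example

```r
library(srnasig)

sim <- simulate_library(sim_config(seed = 42))
sim$library
#> srna_library 'sim42': 1106 alignments, total mapped 1375, 2 sequence(s)

signature_profile(sim$library)
#> signature_profile: 1106 reads
#>   ping-pong z (10-nt overlap): 0.19
#>   phasing z (distance 1):     88
#>   1U fraction:                0.41

percent_dicer_pairs(sim$library)
#> 9.45 % (130 Dicer pairs among 1375 alignments)

loci <- annotate_loci(sim$library, merge_gap = 500,
                      min_rpm = rpm(25, sim$library$total_mapped))
length(loci)
#> 25        # the generator planted 25 loci

m  <- locus_size_matrix(loci, sim$library, len_range = c(12, 35))
cl <- classify_loci(m)
table(cl$class)
#>  pirna_like  dicer_sized  degradation_like  ambiguous
#>          10           10                 5          0

sig <- locus_signatures(loci, sim$library)
median(sig$pingpong_z[cl$class == "pirna_like"], na.rm = TRUE)
#> 24.1
```

Reading the numbers: the library-wide phasing z of 88 reflects the planted
head-to-tail piRNA trains, while the library-wide Ping Pong z is near zero
— Dicer duplexes populate the overlap histogram's background bins, which is
why Ping Pong is scored per locus (median z 24.1 at piRNA-like loci). The
9.45% Dicer-pair rate comes from the siRNA and miRNA loci; a piRNA-only
library scores ~0%. The 25 annotated loci classify into 10 piRNA-like
(Ping Pong + phased), 10 Dicer-sized (siRNA + miRNA) and 5
degradation-like loci, matching what was planted.

Real data enter through `load_genome()` (FASTA) and `load_alignments()`
(SAM/BAM/BED6, 15–35 nt screen), and `run_survey()` drives the whole
workflow from a `survey_config()` and writes loci, histograms, matrices
and a JSON summary.

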