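# meripr — MeRIP-Seq peak detection and comparative m⁶A methylome analysis

N⁶-methyladenosine (m⁶A) is the most abundant internal mRNA modification in
higher eukaryotes. MeRIP-Seq maps it transcriptome-wide by sequencing an
antibody-enriched (IP) library alongside a matched input library from the
same fragmented RNA: methylated regions appear as IP-over-input coverage
peaks, concentrated near stop codons and 3′UTRs. **meripr** implements the
complete downstream analysis of such paired coverage data for comparative
studies (two tissues, two breeds, two treatments), for bioinformaticians
who have aligned coverage and an annotation and want a tested, reproducible
pipeline rather than a chain of one-off scripts.

## What it computes

* **Peak calling.** Sliding windows are tested against a Poisson
  background: the IP read count `x` in a window is scored by the upper tail
  `P(X ≥ x)` with rate `λ = max(λ_genome, λ_±2.5kb, λ_window) · w/ℓ · N_IP/N_input`
  derived from the input track (a local-lambda hierarchy in the spirit of
  MACS, adapted to depth-level RNA data). Significant windows
  (`P ≤ 1e-5`, fold ≥ 2 by default) are merged into peaks with a
  leftmost-argmax summit.
* **Overlap algebra.** Peaks recurring across biological replicates at
  ≥ 50 % overlapping length are kept; between conditions, peaks are
  classified as common (≥ 50 % overlap) or condition-specific, with
  best-overlap pairing and explicit tie rules.
* **Transcript annotation.** Strand-aware spliced coordinate systems from
  GTF; each transcript is partitioned into six non-overlapping segments —
  5′UTR, start codon (±100 nt), CDS, stop codon (±100 nt), 3′UTR, other —
  and each peak is tabulated both summit-exclusively (percentages sum
  to 100) and by multi-membership. Metagene profiles (60 equal bins per
  gene, normalised per kb per million reads, or summit histograms over
  5′UTR|CDS|3′UTR) and peak density across 11 expression groups
  (RPKM > 2) round out the topology analyses.
* **Motif enrichment.** The RRACH consensus (R = A/G, H = A/C/U) is counted
  in ~50-nt windows around the top-1000 peak summits and compared with
  dinucleotide-preserving shuffles of the same windows (empirical P).
* **Differential methylation.** Common-peak counts are M-A normalised by a
  robust Huber regression of `M = log₂(x₁/x₂)` on
  `A = ½·log₂(x₁x₂)`; dynamic peaks (DMPs) are called by an exact
  conditional binomial test on the normalised counts at `P ≤ 0.01` and
  fold ≥ 2.
* **Expression coupling.** RPKM (`count / (kb · millions of reads)`) from
  input coverage, differentially expressed genes by the same exact test
  (`P ≤ 0.05`, fold ≥ 2), and a two-sided Fisher exact test linking DE
  direction to peak presence in each condition.
* **Synthetic data.** `simulate_experiment()` generates a genome,
  multi-exon gene models, expression-proportional Poisson coverage, and
  planted peaks (stop-codon-skewed, RRACH-marked, with common/specific/
  fold-shifted peaks and replicate dropouts) so every stage is testable
  against known ground truth — no download required.

## Worked example

```r
library(meripr)
cfg  <- sim_config(seed = 7, n_genes = 60, genome_size = 6e5)
expt <- simulate_experiment(cfg)

ps1 <- call_peaks(expt$tracks$cond1[[1]]$ip, expt$tracks$cond1[[1]]$input)
ps2 <- call_peaks(expt$tracks$cond1[[2]]$ip, expt$tracks$cond1[[2]]$input)
rec <- recurrent_peaks(ps1, ps2)
rec
#> <peak_set> cond1_rep1_IP+cond1_rep2_IP: 37 peak(s)

models <- longest_coding_transcripts(expt$annotation$models)
segment_table(rec, models)
#> Six-segment peak distribution (37 peaks)
#>      segment count percent multi_count multi_percent
#>        5'UTR     1    2.70           4         10.81
#>  start codon     6   16.22          10         27.03
#>          CDS    14   37.84          20         54.05
#>   stop codon    11   29.73          15         40.54
#>        3'UTR     5   13.51          11         29.73
#>        other     0    0.00          11         29.73

set.seed(7)
motif_enrichment(rec, expt$annotation$genome, models = models, top_n = n_peaks(rec))
#> <motif_enrichment> RRACH in 27/37 summit windows (null mean 17.5), empirical P = 0.001998
```

Here 39 and 38 per-replicate peaks collapse to 37 recurrent peaks; their
summits concentrate in the stop-codon window and CDS end (the planted
topology), and RRACH occurs in 27 of 37 summit windows against a shuffle
mean of 17.5. Continuing across conditions:

```r
rec2 <- recurrent_peaks(call_peaks(expt$tracks$cond2[[1]]$ip, expt$tracks$cond2[[1]]$input),
                        call_peaks(expt$tracks$cond2[[2]]$ip, expt$tracks$cond2[[2]]$input))
cmp <- classify_common_specific(rec, rec2)
cmp
#> <peak_comparison> ...: 30 common pair(s), 7 x-specific, 10 y-specific

fit <- ma_fit(cmp$common$x_count, cmp$common$y_count)
fit
#> <ma_fit> 30 common peaks; M = -0.0015 + 0.0264 A; median Mtilde 0.0034
sum(call_dmps(fit)$dmp)
#> [1] 7
```

The fitted intercept near zero says the two conditions need essentially no
library rescaling; the 7 dynamic peaks are the planted intensity-shifted
common peaks. `run_pipeline(run_config(out_dir, seed))` executes all of the
above plus expression and association stages and writes every table, track
and a checksum manifest; reruns under the same seed are byte-identical.

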