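---
title: "Models and methods behind the meripr m6A methylome pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the meripr m6A methylome pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The data model

MeRIP-Seq pairs an antibody-enriched (IP) library with an input library
from the same fragmented RNA (~100-nt fragments). meripr consumes these
libraries as **per-base depth tracks** (bedGraph or in-memory vectors), not
as reads: alignment is upstream of this toolkit, and every downstream
statistic — window tests, counts, RPKM — is a function of depth. Read
counts are recovered as depth-sum divided by the nominal fragment length
(default 100 nt, configurable), so a 100-nt window at depth 30 corresponds
to 30 fragments. Internal coordinates are 0-based half-open everywhere; GTF
is read as 1-based closed and BED is written 0-based half-open.

# Peak calling

A window of width $w$ (default 100 nt, step $w/2$) with IP count $x$ is
scored against a Poisson rate

$$\lambda \;=\; \max(\lambda_{\mathrm{genome}},\; \lambda_{\pm 2.5\mathrm{kb}},\;
\lambda_{\mathrm{window}}) \cdot \frac{w}{\ell} \cdot
\frac{N_{\mathrm{IP}}}{N_{\mathrm{input}}},$$

where the $\lambda$ terms are input depth rates at three scales, $\ell$ is
the fragment length and the final factor scales the input to the IP library
size. The window is a candidate when the upper tail $P(X \ge x)$ is at most
the cutoff (default $10^{-5}$) **and** the library-scaled fold $x/\lambda$
is at least `min_fold` (default 2). Candidates closer than `merge_gap`
(default 100 nt) merge into one peak, whose counts, fold, P-value and
summit (leftmost position of maximal IP depth) are recomputed on the merged
interval.

This is a deliberate simplification of a ChIP-style caller for depth-level
RNA data: there is no fragment-shift model (depth has no strand structure)
and no fold-band candidate training; the `min_fold` gate plays that role.
One point deserves emphasis: on mRNA coverage the $\pm2.5$ kb neighbourhood
of an exonic window is dominated by zero-coverage introns and flanks, so a
two-scale background ($\lambda_{\mathrm{genome}}$,
$\lambda_{\pm2.5\mathrm{kb}}$) systematically underestimates the local rate
in highly expressed genes and produces confident false peaks with IP ≈
input. Including the window's own input rate
($\lambda_{\mathrm{window}}$, the analogue of MACS's $\lambda_{region}$)
removes this failure mode; on the default simulation it raised caller
precision from ~0.87 to 1.0 without costing sensitivity. The caller
metadata records these choices.

**Assumptions.** Input coverage is an unbiased expression profile;
IP background (outside peaks) is proportional to input; counts in disjoint
windows are approximately independent Poisson. Over-dispersed real
libraries will be anti-conservative at a fixed cutoff — the cutoff is a
tunable, not a guaranteed FDR.

# Overlap algebra

The recurrence and comparison rules all reduce to one primitive:
`overlap_fraction`, the overlap length divided by the length of the
**shorter** interval. The denominator is a genuine design decision — "at
least 50% overlapping lengths" does not say 50% *of which* peak — and the
shorter-interval reading is symmetric and lenient; `reciprocal = TRUE`
switches to the longer interval, i.e. demands the fraction of both.
One-to-many overlaps resolve to the partner with the best fraction, ties to
the leftmost partner. Recurrent peaks are emitted as the interval union of
the matched pair (keeping all signal), with counts pooled across replicates
and the Poisson P-value recomputed on pooled counts; outputs are re-merged
so each sample's peaks stay non-overlapping. Between conditions, every peak
is either paired (common) or specific; the common table carries both sides'
counts, which feed the M-A stage directly.

# Transcript segments and topology

Each coding transcript is partitioned into six non-overlapping segments:
5'UTR, start-codon window, CDS, stop-codon window, 3'UTR, other. The codon
window half-width defaults to **100 nt** — the metagene convention of the
field's standard topology analyses; it is configurable (`w`). Windows are
clipped at transcript bounds; when the CDS is shorter than $2w$ the two
windows would collide, and the contested bases split at the midpoint
between the codon positions so the six labels always tile the transcript
exactly once per base (a property the tests check per base on random
transcripts).

Peaks are tabulated in two modes, side by side. **Summit-exclusive**: the
peak's summit is mapped into its host transcript (longest coding transcript
whose footprint covers the summit) and takes that base's label — one label
per peak, percentages sum to 100. **Multi-membership**: a peak is counted
in every segment any of its bases touches, so percentages may exceed 100.
Both are reported because published six-segment tables whose rows sum past
100% are evidently multi-membership counts, while the exclusive mode is
what gene subgrouping (PeakStart / PeakStop / PeakBoth / others) and the
placement-recovery tests need. Genes with several isoforms use the longest
coding transcript by default (`all_isoforms = TRUE` keeps everything);
non-coding transcripts contribute only to "other".

Metagene profiles come in two flavours: the 60-bin whole-gene profile
(bin boundaries $\lfloor Li/60 \rfloor$, so bins tile the transcript and
un-normalised bin sums conserve total depth exactly; values are depth per
kb of bin per million mapped reads), and the three-part summit histogram
(5'UTR | CDS | 3'UTR rescaled to unit length, normalised within each part).
Transcripts shorter than the bin count are excluded and counted. Peak
density by expression sorts transcripts with RPKM > 2 into 11 equal-count
groups (remainder joins the highest group) — equal-count quantile grouping
is our choice where the grouping rule was open.

# Motif statistic

Rather than re-implementing a de novo motif finder, the package tests the
one motif that matters for m6A: RRACH (R = A/G, the methylated A, C,
H = A/C/U). The top 1000 peaks by significance contribute a
summit ± 25 nt window (oriented by the host transcript's strand); the
statistic is the number of windows containing at least one RRACH match, and
the null is the same count after dinucleotide-preserving shuffles
(Altschul–Erickson random Eulerian walks, implemented in C++ against R's
RNG) of the very same windows, so base and dinucleotide composition are
held fixed exactly. The empirical P-value is
$(1 + \#\{b : \mathrm{null}_b \ge \mathrm{obs}\})/(B + 1)$; with the
default $B = 1000$ the smallest attainable P is $\approx 10^{-3}$, so
choose $B$ to match the significance you need to resolve. Under no planting
the P-value is uniform (checked by KS across 50 simulation seeds). A
position-frequency matrix of the most central match per hit window is
returned for logo plotting. Note RRACH over DNA comprises 12 pentamers
(2·2·1·1·3).

# M-A normalisation and dynamic peaks

Let $x_1, x_2$ be a common peak's counts in the two conditions,
$M = \log_2 x_1/x_2$ and $A = \tfrac12 \log_2 x_1 x_2$ (zero counts take a
+1 pseudo-count). Under the assumption that **most common peaks do not
change**, a robust line through the M-A cloud captures library-size and
intensity-dependent bias; residuals $\tilde M$ are the normalised log2 fold
changes. The fit is iteratively reweighted least squares with Huber
weights, 20 iterations (`MASS::rlm`). $A$ is centred before fitting so the
reported intercept is the fitted normalisation at the typical peak
intensity — i.e. the global log2 library scaling. The uncentred intercept
is an extrapolation to $A = 0$ and inherits an errors-in-variables bias
(Poisson noise moves $M$ and $A$ together within a peak) of order +0.1 at
realistic depths; centring removes exactly that artefact and leaves
residuals, hence all DMP calls, unchanged. A degenerate (constant-$A$) set
falls back to intercept-only normalisation with a warning; fewer than 10
common peaks is an error.

The per-peak test rescales $x_2' = x_2 \cdot 2^{\hat a + \hat b A}$ and
conditions on the total: under the null
$x_1 \mid n = x_1 + x_2' \sim \mathrm{Binomial}(n, \tfrac12)$, with
two-sided $P = \min(1,\, 2\min(P(X \le x_1), P(X \ge x_1)))$. A peak is a
**dynamic methylated peak** when $P \le 0.01$ and $|\tilde M| \ge 1$ (the
"normalised change fold ≥ 2", read two-sided on the normalised fold). This
exact, parameter-free test replaces the original MAnorm Bayesian posterior
deliberately: it is desk-verifiable against direct summation, and its
calibration (null DMP rate ≤ nominal) and power (4-fold shifts at counts
≥ 30) are properties the test-suite measures rather than assumes.

# Expression and association

RPKM is computed exactly as count / (exon-model kb × millions of mapped
reads) from input coverage (counts = exonic depth-sum / fragment length).
Differential expression reuses the conditional binomial machinery with
library-ratio rescaling (defaults $P \le 0.05$, fold ≥ 2) — a defined,
calibratable replacement for an external isoform-deconvolution tool, which
would be out of place on depth-level data. For the methylation-expression
link, the published contingency counts under-determine the 2×2 construction,
so the package embeds an explicit descriptor in every result: the default
construction cross-tabulates peak presence in condition x against presence
in condition y over the DE genes of one direction; an alternative
(direction × presence) is selectable. The Fisher P-value is the classic
two-sided hypergeometric summation (all tables with probability ≤ observed,
with the customary $1+10^{-7}$ tolerance); the odds ratio takes a Haldane
0.5 correction when a cell is zero. `stats::fisher.test` serves as an
independent cross-check in the tests, never as the implementation.

# The synthetic-data generator

`sim_config()` defines the study conditions; defaults are the desk-scale
profile used throughout the tests: 5 Mb genome on two chromosomes, 500
multi-exon coding genes (log-normal 5'UTR/CDS/3'UTR lengths around
200/1200/400 nt), log-normal expression (median RPKM 20, sdlog 1), input
depth 30 per base at the reference RPKM, 150-nt planted peaks at 8-fold
enrichment, placement weights 0.40/0.25/0.15/0.12/0.08 for stop
codon/CDS/start codon/3'UTR/5'UTR, RRACH planted at 80% of summits, 60%
common peaks, 15% of common peaks shifted 4-fold, two conditions × two
replicates with reproducibility 0.85, and 10% DE genes at 4-fold. Where the
study being emulated did not pin a value (gene counts, length and
expression distributions, replicate reproducibility), the defaults are
ordinary values for a mammalian tissue experiment scaled to minutes on one
CPU, chosen once.

What it emulates: expression-proportional Poisson input; IP as the same
rate times the planted fold inside peaks; peaks restricted to the summit's
exon; motif pentamers written into the genome in transcript orientation;
dropouts that unplant a peak from one random replicate; determinism — a
fixed seed reproduces byte-identical FASTA/GTF/bedGraph outputs.

What it does **not** emulate: over-dispersion beyond Poisson, GC and
fragment-composition bias, splice-junction reads, antibody off-target
binding, multi-isoform expression, or peaked (non-rectangular) enrichment
profiles — planted peaks are depth plateaus, optionally smoothed by a
100-nt moving average (`smooth = TRUE`, off by default to keep ground truth
crisp). Two consequences are worth knowing. First, passing recovery tests
here bounds algorithmic correctness, not robustness to real-library
artefacts. Second, on a plateau the argmax summit is uniform over the
plateau rather than centred, so called summits jitter ±75 nt around the
planted site; summit-based tabulations of *called* peaks therefore
attenuate the planted stop-codon share (roughly 40% planted → low-30s%
called), and the placement-recovery test measures planted summits, where
the tabulation is exact. This attenuation also exists in real callers.

# Numerical choices and degenerate inputs

* Poisson/binomial/hypergeometric tails use `stats` (`ppois`, `pbinom`,
  `dhyper`); P-values are clamped away from zero only where logs are taken
  for BED scores.
* Ties: summit argmax → leftmost; best-overlap partner → leftmost; longest
  transcript per gene → lexicographically first id.
* Empty peak set → segment table of zeros with a warning; empty input
  library or a reference missing from the input → error naming it;
  `top_n` above the available peaks → use all, warn; windows wider than the
  transcript → clipped, never an error.
* The test-suite runs the full study profile where a criterion demands it
  (caller recovery, pipeline determinism) and reduced profiles elsewhere
  (e.g. 60-gene annotations for interval oracles, 3,200 single-peak genes
  for placement recovery, 50 seeds × 50 genes for motif null calibration)
  — sizes chosen as the smallest that leave the measured proportions'
  sampling error well inside the asserted bands.

# Known limitations

Poisson windows understate variance on real libraries; the caller reports
raw P-values, not FDR. The recurrence union can chain nearby peaks through
a long partner. Gene-level counts ignore isoform structure. The Fisher
association inherits whatever construction is chosen — compare both
descriptors before interpreting. And all calibration statements are
statements about the generator's assumptions, not about any particular real
dataset.
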