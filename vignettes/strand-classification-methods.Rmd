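---
title: "Strand-specific methylation calling from MeDIP-Seq: model and methods"
author: "medipstrand"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strand-specific methylation calling from MeDIP-Seq: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medipstrand)
```

## The problem

MeDIP-Seq enriches single-stranded, 5-methylcytosine-carrying DNA fragments
with an antibody before sequencing. Because the library protocol ligates
forked adaptors directionally *before* denaturation, the first mate of each
pair is always sequenced from the adaptor retained on the immuno-captured
strand. The strand of a first-mate alignment therefore reports the strand of
the underlying methylation: forward alignments come from plus-strand 5mC,
reverse-complement alignments from minus-strand 5mC. Standard peak callers
ignore this, so symmetric (CG dyad, both strands) and asymmetric
(hemimethylated, often CHG/CHH) methylation are conflated in their output.
`medipstrand` decomposes each called peak into one of three classes — plus-,
minus- or double-stranded methylation — from the strand split of its
first-mate reads. This matters most for genomes such as the honeybee's where
asymmetric methylation predominates.

## The decision rule

Let $Y$ be the number of filtered first-mate reads overlapping a peak, with
$Y_+$ aligned forward and $Y_-$ aligned in reverse complement,
$Y = Y_+ + Y_-$. Read counts at a fixed locus are modelled as Poisson. For an
integer candidate rate $\lambda$ the likelihood of an observed count $y$ is

$$ l(\lambda) = \Pr[Y = y \mid \lambda], $$

maximised over a candidate set at $\Lambda = \arg\max_\lambda l(\lambda)$.
The *likelihood set* at cutoff $\alpha \in (0,1)$ is

$$ LS_\alpha = \{\lambda : l(\lambda) / l(\Lambda) \ge \alpha\}, $$

the candidate rates that explain the observed count nearly as well as the
best one. For each peak the candidate set is every integer from
$\min(Y_+, Y_-)$ to $\max(Y_+, Y_-)$, and one likelihood set is built for
each strand count over that shared range. If the two sets intersect, some
rate is simultaneously plausible for both strands and the peak is called
double-stranded; otherwise the strand with the larger count wins. Equal
counts give identical sets, so ties cannot reach a single-strand branch.

```{r worked}
classify_peak(60, 40, alpha = 0.1)
```

With $Y_+ = 60$, $Y_- = 40$ the sets $\{45..60\}$ and $\{40..55\}$ overlap
in $\{45..55\}$ and the peak is double-stranded, even though
$\theta = Y_+/Y = 0.6$; at the same 3:2 ratio but higher depth the sets
narrow relative to the count gap and the call flips to single-stranded.
This depth dependence is intended: more evidence is required before a
single-strand claim is made.

### Why the likelihood is evaluated at $\lambda$ for both strands

A natural alternative parameterisation thins the peak rate by the observed
plus fraction $\theta$, scoring $Y_+$ against $\mathrm{Poi}(\lambda\theta)$
and $Y_-$ against $\mathrm{Poi}(\lambda(1-\theta))$. Under that scoring the
two thinned rates are re-centred onto their own observed counts, the two
likelihood sets intersect only by coincidence, and the decision rule loses
its meaning of "is one shared rate plausible for both strands". We therefore
evaluate both strand counts against the *same* candidate $\lambda$ over the
shared range — this is what makes the 60/40 example above behave as shown —
and report $\theta$ as a descriptive statistic only.

### Numerical choices

* All likelihood arithmetic is in log space via `dpois(log = TRUE)` (the
  log-gamma form of the factorial), so counts in the thousands do not
  overflow; ratios are compared as log differences against $\log\alpha$.
* The cutoff is inclusive ($\ge \alpha$), which is what places the boundary
  rates (likelihood ratio just above 0.1, e.g. 0.104 at $\lambda = 45$ for
  $y = 60$) inside the set.
* The zero-rate boundary is exact: $\Pr[0 \mid 0] = 1$ and
  $\Pr[y > 0 \mid 0] = 0$.
* A peak with $Y = 0$ cannot be assessed and is reported `unclassified`
  with a low-depth flag rather than dropped or crashed on.
* The Poisson likelihood is unimodal in $\lambda$, so every likelihood set
  is a contiguous integer range; the tests assert this over randomised
  inputs and against a brute-force enumerator written from first
  principles.

## Tunable parameters

* `alpha` (default **0.1**, dimensionless in (0,1)): the customary
  likelihood-ratio cutoff. Smaller values widen the sets and shift calls
  toward double-stranded; the default is the conventional "an order of
  magnitude less likely" threshold.
* `min_depth` (default **0** in `classify_all()`, **12** first-mate reads in
  the end-to-end `call_strands()` and the CLI): below this total depth a
  call is withheld (`unclassified`) but the peak and its likelihood sets
  are still reported, so no peak silently vanishes. Twelve reads is the
  depth below which the decision rule is dominated by shot noise.
* `min_mapq` (default **10**): alignment filter, matching common MeDIP
  post-processing practice; duplicates are consumed from the BAM flag
  (marking is an upstream step), and secondary/supplementary records are
  always excluded to prevent double counting.
* `flank` (default **2000** bp): width of the upstream/downstream gene
  flanks in the feature analysis.
* `half_width` (default **100** bp): splice-site windows extend this far to
  either side of each exon–intron boundary. There is no canonical window
  size for junction methylation; 100 bp keeps windows well inside typical
  exon/intron lengths while still capturing peak overlap. It is exposed as
  a parameter because the choice is genuinely open.
* `prior_shape`, `prior_rate` (default **0.001, 0.001**): a vague conjugate
  gamma prior for the per-1000-instances methylation rate; with any
  realistic count the posterior is data-dominated, and the
  prior-vanishing limit (posterior mean → count/exposure) is tested.
* `n_draws` (default **10 000**) and `seed`: the credible interval is taken
  from seeded posterior draws; the seed is recorded in the result so the
  interval is reproducible. (The closed-form gamma quantiles would do; the
  simulated interval generalises to derived quantities such as the
  percentage shares and is cross-checked against `qgamma` in the tests.)

## Strand-aware overlap counting

All downstream analyses reduce to counting interval overlaps: two features
overlap when they share a sequence name, overlap by at least one base, and —
when strand is respected — have compatible strands, where "both" (`*`) is
compatible with everything and `+`/`-` only with themselves or `*`. This is
exactly the overlap contract of Bioconductor's `GenomicRanges`, which
provides the engine behind `count_overlaps()`; the tests hold it against a
naive all-pairs scan. Read-to-peak assignment uses the same any-overlap
convention (an alternative 5'-end mode is available via `count_strands()`
inputs prepared accordingly). Peaks are classified independently; caller
regions are neither merged nor re-centred.

## The synthetic data generator

`simulate_medip()` produces a complete, seed-reproducible test bed: a random
two-scaffold genome (500 kb each), 80 multi-exon genes (2–6 exons of
150–400 bp, introns of 500–1500 bp), and by default 100 non-overlapping
peaks of 260–600 bp (median near 430 bp, typical of MACS2 methylation
windows) assigned truth classes plus/minus/both at 0.4/0.4/0.2. Each peak
draws Poisson(`depth_mean` = 50) first mates on every methylated strand and
Poisson(`epsilon` × depth) on an unmethylated strand (`epsilon` = 0.02
models antibody cross-capture and makes recovery non-trivial; 0 gives the
clean idealisation). Background reads (1 per kb) are scattered uniformly on
random strands. Sixty per cent of peaks are genic; genic single-stranded
peaks are centred on a splice junction of a host gene whose strand realises
the configured sense/antisense orientation (`antisense_bias`, default 0.5 =
strand-neutral null). Peak sequence is composition-planted so the methylated
strand is C-rich, making the library-level per-cycle C:G disparity visible
in the first-mate FASTQ. Reads are emitted as already-aligned,
coordinate-sorted proper pairs — the tool consumes alignments, so the
aligner itself is deliberately outside the simulated surface.

What the generator does **not** emulate: fragment-length variation,
sequencing error, mappability structure, duplicated reads, overlapping gene
models, isoform diversity, and peak-caller boundary noise. Passing the
recovery tests therefore demonstrates the correctness of the decision rule
and of the counting machinery under the stated model, not robustness of
MeDIP-Seq itself to alignment artefacts on real genomes.

## Downstream analyses

* **Width bias.** Peaks are split into width groups at the 50% and 95%
  quantiles (groups of 50/45/5% of peaks) and class composition is tested
  for independence of width with Pearson's chi-squared test; a warning is
  attached when expected cells fall below 1.
* **Concordance with single-base calls.** Within each peak class, stranded
  5mC calls (e.g. reshaped bisulfite-caller output, support ≥ 3 reads) are
  counted per peak on each strand and the per-peak plus/minus counts are
  compared with a paired two-tailed t-test. Identical per-peak splits are
  reported as p = 1 (no evidence against the null) rather than as a
  degenerate t statistic.
* **Splice-site asymmetry.** Single-stranded peaks overlapping junction
  windows are labelled sense/antisense by comparing peak strand with the
  transcript strand of one window per junction (the question is about
  strandedness, not exonic vs intronic position), and equality of the two
  proportions is tested with a two-tailed one-sample proportion test with
  continuity correction.
* **Feature-normalised distribution.** Per feature set, overlap counts per
  1000 instances are modelled with the conjugate gamma–Poisson update
  (posterior Gamma(prior + count, prior + instances/1000)), summarised by
  the posterior mean, a simulated 95% credible interval, and percentage
  shares across the four gene-anatomy features.

## Problem sizes in the test suite

The suite verifies the classifier against a brute-force enumerator on every
count pair up to 200 (≈20k ordered pairs plus mirror checks), runs the set
invariants on 10⁴ randomised pairs, and exercises the full BAM-to-calls
pipeline on simulations of 500 peaks at depth 50 (single-strand recovery
≥ 95%) and 300 peaks at `antisense_bias` 0.9 (direction recovered at
p < 10⁻⁴ for both junction types). These sizes were chosen to give the
recovery estimates comfortable margins while keeping the default test run
fast on a laptop.

## Known limitations

* The classifier needs strand-preserving paired-end libraries; single-end
  data carry no recoverable first-mate signal and are rejected explicitly.
* Calls are per peak: a wide region genuinely mixing single- and
  double-stranded methylation is summarised by one label (the width-bias
  test exists to check whether this matters in a given dataset).
* Methylation *level* (fraction of methylated molecules) is out of scope;
  the model concerns the strand of the signal, not its intensity.
* Improper pairs are kept by default (any mapped, high-quality first mate
  counts); `proper_pairs_only = TRUE` tightens this at the cost of
  discarding reads near structural breakpoints.
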