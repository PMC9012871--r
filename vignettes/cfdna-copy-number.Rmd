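---
title: "Tumor-fraction inference from shallow WGS of cell-free DNA: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tumor-fraction inference from shallow WGS of cell-free DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfCNA)
```

# The problem

Plasma cell-free DNA (cfDNA) from a cancer patient is a mixture: a fraction
`tf` (the tumor fraction) of fragments originates from tumor cells, the rest
from normal cells. Tumor genomes carry segmental copy-number alterations
(CNAs), so tumor-derived fragments are over- or under-represented in altered
regions. At shallow whole-genome sequencing depth (< 1x) individual loci are
uninformative, but read depth aggregated over large genomic bins (hundreds
of kilobases) is precise enough to detect CNAs and, from their magnitude, to
quantify `tf`. cfCNA implements this analysis end to end for cohorts like a
canine splenic-mass study: healthy controls, subjects with benign lesions,
and subjects with malignant vascular tumors, sampled before and after
surgery.

# Depth model

A clonal alteration to integer copy number $c$ in a diploid genome shifts
the expected log2 depth ratio of the bins it covers to

$$\mu(c) = \log_2\frac{tf \cdot c + (1 - tf)\cdot 2}{2},$$

implemented as `expected_log2(tf, c, ploidy)`. At `tf` = 0.1 a single-copy
gain shifts depth by only `r round(cfCNA::expected_log2(0.1, 3), 3)` log2
units, which is why every upstream normalization step matters:

1. **Binning.** Two scaffolds are supported: fixed-width bins (500 kb
   default) and a fixed total count of bins (5500 default) whose boundaries
   equalize *mappable* bases per bin. Bins never span chromosomes; the
   equal-mappable scheme apportions bins to chromosomes by largest-remainder
   rounding of usable-base quotas and places boundaries at cumulative
   usable-base quantiles, snapping to the left edge of unmappable runs.
2. **GC correction.** Library preparation biases depth smoothly with bin GC
   content. A loess curve (span 0.3, degree 2) of count versus GC over
   unmasked autosomal bins is divided out; totals are rescaled so counts
   are conserved.
3. **Panel of normals.** Bin-specific effects that GC does not explain
   (mappability structure, recurrent artifacts) are removed by dividing by
   a per-bin reference level built from healthy-plasma controls — either
   the per-bin median of GC-corrected, library-size-scaled controls
   (default) or their pooled sum, mirroring a merged-control alignment.
   Bins where any control has zero depth are masked rather than imputed.
4. **Centering.** Log2 ratios are centered on the *mode* of their
   distribution (kernel density peak), not the median. With a quarter of
   the genome gained, the median sits measurably off the copy-neutral
   level and biases `tf` downward; the mode stays on the neutral peak as
   long as neutral remains the most common state. The median is used as a
   fallback for fewer than 200 valid bins or degenerate input, and is
   available by option.

# The two segmentation arms

**CBS arm.** Circular binary segmentation: per chromosome, the maximal
two-sample t statistic over circular arcs is tested against a permutation
null (`alpha` 0.01, 1000 permutations, early stopping once significance is
impossible); significant arcs split the segment recursively. Segment states
(`gain`/`neutral`/`loss`) come from log2 thresholds (±0.2 default, roughly
one copy at ~30% tumor fraction), and adjacent same-state segments are
merged with bin-count-weighted means. There is no undo/pruning pass; an
optional merge-by-threshold flag covers that role.

**HMM arm.** A six-state hidden Markov model over bins in genome order:
clonal copy numbers {0, 1, 2, 3} plus subclonal {1, 3}, whose emission
locations are tied to `tf` through $\mu(c)$ (subclonal states use
`tf * sp`, one shared subclone prevalence `sp`). Emissions are Student-t
(df 3, robust to outlier bins) with one shared scale. EM alternates exact
forward–backward posteriors with coordinate-ascent M-steps (bounded 1-D
`optimize` for `tf`, `sp`, the scale, and a baseline shift), so the
penalized likelihood is non-decreasing by construction — the test suite
asserts this on every iteration. The fit is repeated from the initial
normal-proportion grid {0.7, 0.8, 0.9, 0.95, 0.99}; the highest-likelihood
solution wins, ties going to the *lower* tumor fraction. `tf` is searched
in [0.005, 0.6]; a copy-neutral sample therefore reports the floor 0.005,
below the 3% detection limit this class of estimator is quoted at.

## Why the parameter space is deliberately restricted — and two degeneracies

Ploidy is fixed at 2, copy numbers capped at 3, and subclonal options
limited to {1, 3}: with free ploidy, shallow-WGS mixtures admit spurious
high-tumor-fraction solutions with inferred ploidy 3 and no visible CNAs.
Two further degeneracies surfaced during parameter-recovery testing on
synthetic data, and two model components exist specifically to break them:

- **Halving degeneracy.** A single-copy loss at tumor fraction $t$ is
  *emission-identical* to a homozygous deletion at $t/2$
  ($\log_2(1-t/2)$ in both cases), and a low-prevalence subclonal state
  duplicates the neutral level. Left alone, maximum likelihood reliably
  picked the halved solution. A per-bin state-occupancy log-prior
  (penalized EM) down-weights homozygous deletion (weight 0.02 against 0.3
  for each of copy 1/2/3) and subclonal states (0.04 each) — reflecting
  that multi-megabase homozygous loss is rare in circulating DNA — and
  removes the spurious optimum without touching the emission model.
- **Baseline shift.** Even mode-centering leaves a small residual offset of
  the neutral level. A free location parameter (bounded to ±0.1 log2)
  absorbs it inside the EM rather than forcing `tf` to compensate.

Two numerical decode details: the self-transition probability defaults to
0.999, not an extreme value like 0.9999 — each state switch costs
$\ln((1-p)/5)$ nats on the Viterbi path, and at 0.9999 that cost prices
segments shorter than ~40 bins out of being called, which in turn biases
`tf` down by absorbing real CNAs into the baseline. And states whose
expected shift lies within half an emission scale of neutral are collapsed
into neutral *for decoding only*: they are statistically indistinguishable
at the data's noise level, and without the collapse the Viterbi path flips
arbitrarily among duplicates, inflating the fraction of genome altered.

# Method comparison, recurrence, cohort statistics

`summarize_segments` computes per-segment length and the SD (denominator
n−1) of member-bin log2 values; `compare_methods` pools one SD per segment
from each arm and applies a two-sided Mann–Whitney U test. All rank tests
(`rank_sum_test`, `paired_signed_rank`, `kruskal_wallis`) use exact
enumeration at small n (≤ 8 per group, ≤ 12 non-zero pairs) and midrank
normal approximations with continuity correction beyond, so small-sample
p-values are reproducible exactly. ROC AUC is pair counting with half
credit for ties — identical to U/(n₁n₂), which the tests assert.

Cohort recurrence uses a G score per bin and direction: the mean over
samples of the covering segment's matching-direction amplitude (zero
otherwise), i.e. frequency × mean amplitude. Significance comes from a
cyclic-shift permutation null — each sample's per-bin amplitude vector is
rotated within each chromosome by an independent uniform offset — which
preserves segment-length structure and per-sample burden while destroying
positional recurrence; this is a conservative null for serially correlated
CNA data. p-values use add-one smoothing, q-values are Benjamini–Hochberg
across bins, and regions are maximal runs with q ≤ 0.25 (configurable).
One sample per subject enters (the highest tumor fraction, earliest date on
ties). Calibration is tested by KS against uniform on a fully null cohort,
with tested bins thinned beyond the segment correlation length (p-values of
neighboring bins covered by the same segments are not independent, and a
naive bin-level KS test would reject for that reason alone).

# Fragment-size profiling

Histograms are integer-binned; the modal size is the raw argmax with ties
toward the smaller length. At realistic mono-nucleosome peak width (sd
~10 bp) the argmax of a 100,000-fragment histogram wanders ±1–2 bp by
sampling noise alone, so cohort-level statements use the average of
per-sample modes — the same summary the motivating study reports (165.6 bp
across nine healthy dogs). The 10 bp periodicity score detrends the
log-density in the 100–160 bp band (21-bp moving average), takes discrete
Fourier power at 1/10 bp⁻¹, and divides by the power at neighboring
periods (5–20 bp, excluding ±1 bp around the target). The reference is a
10%-trimmed mean of neighbor powers: a plain median has a heavy null tail
(the score exceeded 4 in ~6–7% of white-noise draws), while the trimmed
mean concentrates and keeps one genuine spectral line from inflating the
reference. The detection threshold is 5, set a priori so the white-noise
false-detection rate is below the stated 5% bound.

# The synthetic-data generator: what it emulates, what it does not

`sim_config()` states the world once: a 20-chromosome × 60 Mb (~1.2 Gb)
genome; a smooth GC field in [0.3, 0.6]; mappability 1 with ~2% of the
genome in unusable runs; 9 healthy controls; ~400 fragments per 500 kb bin
(~0.5× coverage equivalents); linear GC bias (slope 0.3); negative-binomial
bin counts targeted at log2 noise sd 0.06; cohort tumor fractions drawn
from truncated normals with the study's group parameters — benign
mean 0.032 sd 0.034 (n 14), malignant mean 0.112 sd 0.091 (n 25) — and a
0.7 post-surgery reduction, the scale of the observed 11.0% → 7.9% drop.
CNA truth segments are 15–60 Mb, chromosome-arm to whole-chromosome scale,
matching the broad alteration landscape of the malignant vascular tumors
emulated; only the genome *fractions* altered (25% gained, 10% lost) were
stated upstream, so the length scale is this package's biological choice.
Fragment lengths mix discretized normals at 166/332/498 bp (weights
0.8/0.15/0.05) with a sub-mononucleosomal ladder (8% of fragments, decaying
below 156 bp) carrying a 10 bp cosine comb (amplitude 0.25) via rejection
sampling.

Two honesty notes. At 400 fragments per bin, Poisson counting noise alone
is 0.072 log2 units — above the nominal 0.06 target — so the generator
clamps overdispersion at zero rather than fabricating sub-Poisson counts;
every green test holds under this attainable noise floor. And the
generator does *not* emulate: real mappability structure (k-mer
self-alignment), fragment-level GC effects, inter-chromosomal depth
covariance, sample contamination, or subclonal CNA heterogeneity. A green
end-to-end test therefore establishes that the pipeline's inference is
correct *under its own stated model*, not that real canine plasma behaves
this way.

# Orchestration

`run_pipeline()` takes a single validated config (flat-key JSON via
`jsonlite`; unknown keys are rejected) and sequences bins → depth → panel
→ normalize → both arms → metrics → recurrence → cohort statistics,
writing a manifest that records every configurable parameter and the seed.
`run_demo()` simulates a full cohort and runs the pipeline on its file
representation; with a fixed seed the outputs are byte-identical across
reruns, which the test suite asserts. Demo permutation counts are reduced
(200) to keep the run in interactive time; analysis defaults are 1000.

# Known limitations

- Tumor fraction and subclone prevalence are entangled: a clonal CNA at
  low `tf` and a subclonal CNA at higher `tf` can be near-equivalent. We
  report `tf = 1 − n` and expose `sp` separately rather than folding it in.
- No allele-fraction (BAF) information: balanced events and
  copy-neutral LOH are invisible by construction.
- The state-occupancy prior is a bias-variance trade: it suppresses
  genuine multi-megabase homozygous deletions along with the spurious
  solutions they imitate.
- Sex chromosomes are binned but excluded from likelihoods by default
  (mixed-sex cohorts); X-linked CNAs are not assessed.
- The CBS arm's copy-state thresholds (±0.2 log2) are declared defaults,
  not estimates; at tumor fractions below ~15% single-copy events fall
  below them and are labeled neutral even when the changepoints are found.
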