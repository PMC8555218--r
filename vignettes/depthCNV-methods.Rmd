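---
title: "Read-depth CNV calling with consensus-driven parameter optimization"
author: "depthCNV authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Read-depth CNV calling with consensus-driven parameter optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages(library(depthCNV))
```

# The problem

Germline copy-number variants (CNVs) — deletions and duplications of
genomic segments — are routinely screened from targeted (TS) or
whole-exome (WES) capture sequencing by read-depth analysis: a sample
carrying a heterozygous deletion yields roughly half the expected read
count over the deleted targets. Read-depth callers are, however, highly
sensitive to their tuning parameters, and the appropriate tuning differs
between capture designs, sequencing depths and cohorts. The conventional
way to tune them is against wet-lab truth (MLPA or aCGH), which is slow
and costly.

depthCNV implements the alternative: build an *in silico* validation set
from the consensus of several independent callers run on the same cohort,
then grid-search the depth caller's parameters against that consensus to
maximize sensitivity, and finally re-call the cohort with the optimized
parameters. Because concordant calls from independent algorithms are very
rarely all wrong, the consensus has (near-)perfect precision, and although
it misses many true events, it is exactly the kind of truth a sensitivity
optimization needs.

# The caller

The internal caller is a transparent read-depth caller exposing exactly
the three parameters the optimizer searches:

* **minCorrelation** (default 0.98) — a test sample's reference set is
  drawn from its batch: candidates are ranked by Pearson correlation of
  raw count profiles over the active targets, those below the threshold
  are discarded, and at most 10 are kept (reference sets larger than
  about 10 samples stop improving the baseline). Samples with no
  qualifying reference are no-calls for the whole batch. Related samples
  (same `family` in the sample sheet) are always excluded so a CNV shared
  within a family is not normalized away. Correlation is computed on raw
  counts; the dominant shared signal across capture samples is the
  per-target efficiency profile, which spans an order of magnitude and
  makes well-behaved samples correlate above 0.98.
* **minCoverage** (default 100 reads) — a target whose median count
  across the batch falls below the threshold is dropped; a sample whose
  median count across the (pre-drop) targets falls below it is a no-call.
  Sample medians are evaluated before target dropping, so the two
  filters commute deterministically. Both filters can be toggled.
* **transitionProb** — the hidden-Markov segmentation parameter, below.

**Reads ratio.** For test sample $s$ with reference set $R$, counts are
library-size normalized over the active targets
($\tilde c_{sr} = c_{sr} / \sum_r c_{sr}$) and the per-target ratio is
$x_r = \tilde c_{sr} / \operatorname{median}_{j \in R} \tilde c_{jr}$,
which is $\approx$ CN/2 on diploid regions. Targets whose reference
median is zero are no-calls for that sample.

**Segmentation.** A three-state HMM (DEL, NORMAL, DUP) on the ratio
scale with state means 0.5, 1.0, 1.5 and Gaussian emissions. The per-ROI
emission SD is the standard deviation of the reference samples' own
normalized ratios at that target, floored at 0.05; this is a deliberately
simple, deterministic emission model — the optimizer needs parameter
sensitivity, not an exact overdispersion likelihood, and the exhaustive
enumeration oracle in the test suite verifies the decoder rather than the
model. Transitions: NORMAL enters each CNV state with probability $t$
(`transitionProb`, default 0.01 — a deliberately conservative default);
CNV states return to NORMAL with probability 1/3 (expected event length 3
targets; fixed, not optimized) and cross directly between DEL and DUP
with probability $10^{-6}$. The initial distribution is $(t, 1-2t, t)$.
The most likely path is decoded by Viterbi per chromosome; ties in the
decoder resolve toward the lower state index (DEL first), which random
ratios never exercise. Single-target chromosomes are paths of length 1.

**Calls.** Maximal runs of consecutive same-state non-normal targets
become one call spanning the run; its reads ratio is the run mean and its
copy number follows the banded mapping: ratio $\le$ 0.1 $\to$ 0,
$\le$ 0.8 $\to$ 1, $\le$ 1.2 $\to$ 2, $\le$ 1.8 $\to$ 3, $\le$ 2.2
$\to$ 4, above that twice the ratio rounded half-up (the source of the
mapping prints no rounding rule; half-up is this package's choice). Call
spans are clipped to target boundaries — bait-level resolution is all a
per-target method can honestly claim.

**Batching and sex.** Calling runs separately in female and male batches
so sex-chromosome baselines are homogeneous; with fewer than 5 samples of
either sex everything runs in one batch and X/Y calls are flagged
unreliable. A `batch2` mode keeps autosomes mixed and splits only X/Y.
Unknown sexes are inferred from coverage: male when the mean chrY count
reaches 0.25$\times$ the autosomal median and the mean chrX count is at
most 0.75$\times$; female when chrY falls below 0.25$\times$; ambiguous
profiles resolve to female with a warning. The rule compares raw means
against a median, so it presumes sex-chromosome targets of roughly
comparable capture efficiency to autosomal ones; with very few,
badly-behaved Y targets, provide sexes explicitly.

# The consensus validation set

External call sets enter as 5-column BED (chrom, start, end, DEL|DUP,
sample). Per (sample, type, chromosome), calls of the retained callers
are grouped into connected overlap components; within a component each
caller contributes the fragment with the largest overlap (leftmost on
ties — callers occasionally fragment one event), and the mutual
intersection is validated when it covers at least 60% of at least one
contributing call *and* is at least as long as the mean target size. The
60% rule is read as "of at least one caller", not reciprocally — that is
the more faithful reading of a consensus anchored on any one call set —
and the validated span is the intersection (the most conservative of the
candidate spans), clipped to the target footprint. Callers reporting no
CNV at all are discarded first; at least two non-empty call sets are
required.

The union of validated calls, merged where overlapping, defines the
validated regions. Every cohort sample is assigned a state at every
validated region — its validated call's type where one overlaps (if two
overlap, the larger overlap wins), otherwise NORMAL. This full matrix is
the optimizer's truth: without the normal-state augmentation the
optimizer would see only positives and degenerate to call-everything.

# Optimization

The grid search evaluates caller parameter combinations (at most 22
values per axis; the default grid is 12 correlation $\times$ 10 coverage
$\times$ 10 transition values, each containing its default) by re-calling
the cohort and scoring per (sample, validated region) against the
validation states. The objective is sensitivity; ties break toward higher
F-score (preventing call-everything optima), then higher specificity,
then proximity to the defaults in grid-rank space, then grid order — a
fully deterministic chain. Because the defaults are grid members, the
selected optimum can never score below them. A coordinate-descent mode
(sweep one axis at a time, two passes) exists for large grids; it is a
heuristic and is never better than the full grid.

Evaluation during optimization is restricted to validated regions — the
universe where the consensus provides truth — rather than the full
target. No-calls count as NORMAL by default (`as_normal`), matching a
diagnostic reading in which uncalled regions are negatives that would
need orthogonal confirmation; an `excluded` policy removes them from the
universe instead.

# Benchmarking

Evaluation units are (sample, region) pairs, each carrying exactly one
label; when disjoint DEL and DUP calls of one sample fall inside one
merged validated region, the larger overlap labels the unit (overlapping
opposite-type calls remain a hard error — they violate the call-set
contract). A unit whose truth is non-normal scores TP on an exact match
and
FN otherwise — a wrong-type call (DEL for DUP) is counted as a miss, not
additionally as a false call, because a single-label scheme must pick one
category and "the caller missed the validated CNV" is the honest one
(configurable to double-count). Normal-truth units score TN/FP. The five
metrics are sensitivity, specificity, PPV, NPV and F-score (harmonic mean
of PPV and sensitivity); any ratio with a zero denominator is undefined
(NA), and values are kept at full precision, displayed at 4 decimals.

# The synthetic cohort generator

The generator emulates a mid-sized diagnostic capture cohort, not any
particular dataset: 48 samples (half female, 4 related pairs), 300
targets of 120–400 bp over four autosomes plus chrX/chrY, negative-
binomial counts with mean
$\mu_{sr} = \bar d \cdot d_s \cdot e_r \cdot \mathrm{CN}_{sr}/2$
(diploid baseline — male chrX sits near half depth, female chrY near
zero), $\bar d = 250$, per-sample depth factors $d_s \sim N(1, 0.1)$
truncated at 0.2, per-target efficiencies
$e_r \sim \mathrm{LogNormal}(0, 1)$ and NB size 200. Two of these choices
carry the realism the pipeline depends on: the order-of-magnitude
efficiency spread is what makes raw-count profiles of unrelated capture
samples correlate above the 0.98 default (with a narrow spread the
correlation filter would no-call everyone), and at 250$\times$ the NB
size of 200 gives roughly twice Poisson variance, typical of capture
data. About a quarter of targets fall below the default 100$\times$
median-coverage filter, which is what gives the coverage axis of the
optimizer something real to trade off. Truth events arrive at 0.5 per
sample (Poisson), geometric lengths with 40% single-target events, 60%
deletions (10% of autosomal deletions homozygous), never overlapping
within a sample and respecting each sex's ploidy.

Surrogate caller outputs are truth plus noise — per-event dropout (5%),
boundary jitter ($\pm$1 target, constrained so a call always keeps at
least one true target: callers disagree about boundaries, they do not
translate a call off its locus) and per-unit false calls (0.5%, the
order of the per-target false-positive frequencies published for
well-behaved diagnostic panels) — rather than independent re-calls from
the counts, so consensus tests isolate the consensus logic from caller
quality. Validated calls are matched back to truth with a one-target
slack so that a jittered boundary on a real event is never mistaken for
an invented event.

What the generator does *not* model: GC-content bias, mappability,
batch effects between sequencing runs, mosaicism, and read-level noise.
Passing tests on these cohorts therefore demonstrate the pipeline's
logic — normalization, segmentation, consensus, optimization direction —
under realistic dispersion and depth structure, not calling performance
on real libraries.

# Problem sizes and numerical choices

The test suite exercises cohorts of 10–30 samples over 50–320 targets,
and the optimization checks use a reduced 5 × 4 × 6 grid on 30-sample,
300-target cohorts; these sizes give the stochastic assertions
comfortable margins while keeping a full run of the suite in the minutes
range. Everything is deterministic given a seed: simulation and
surrogate noise consume seeds explicitly, the caller and optimizer are
seed-free deterministic algorithms, and re-running the batch pipeline
with one configuration reproduces byte-identical artifacts (the MANIFEST
records MD5 checksums; the run log carries no timestamps for exactly this
reason).

Degenerate inputs are handled explicitly: empty ratio vectors decode to
empty paths; an all-dropped batch is an error that no-calls its units
without aborting other batches; an empty validation set refuses
optimization with a pointer to the consensus step; zero-denominator
metrics are NA, never 0/0 artifacts.

# Known limitations

* The caller's Gaussian emission on the ratio scale understates the
  heavy lower tail of count ratios at low depth; the coverage filter is
  doing part of the emission model's job.
* Consensus coordinates are intersections; a caller systematically
  over-extending boundaries shrinks validated events but cannot move
  them.
* Sensitivity-maximizing optimization will happily trade specificity
  within what the tie-break chain allows; on panels where false
  positives are expensive, optimize `f_score` instead (supported).
* Sex-chromosome calls in mixed batches are flagged, not suppressed;
  treat them as screening hints only.

# Pipeline and artifacts

`runBatch()` wires the stages: default-parameter calling, consensus with
the configured external call sets, grid optimization, final calling, and
a metrics table (default vs optimized against the validation set). Every
artifact is a plain text file re-readable by the package's own readers,
and the final calls are also written as an annotation-ready 5-column BED
(hook only; annotation itself is out of scope). A thin command-line
front-end with subcommands `simulate`, `call`, `consensus`, `optimize`,
`benchmark` and `batch` ships in `inst/scripts/depthcnv.R`.
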