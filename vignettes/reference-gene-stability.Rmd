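---
title: "Evaluating reference-gene stability for RT-qPCR normalization"
author: "CtStability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating reference-gene stability for RT-qPCR normalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CtStability)
```

## The problem

Quantitative RT-PCR reports expression as threshold cycles (Ct): the
PCR cycle at which fluorescence crosses a detection threshold. One
cycle corresponds to roughly one doubling of template, so Ct is a
negative log2 expression scale. Because the amount of input RNA,
extraction efficiency and reverse-transcription yield vary between
samples, target-gene Ct values are normalized to *reference*
("housekeeping") genes assumed stable across all experimental
conditions. That assumption fails surprisingly often — classic
references such as *Actb* or *Gapdh* are themselves regulated in many
tissues and injury models — and normalizing to a regulated reference
manufactures spurious differential expression or masks real
regulation. Before any target-gene analysis, candidate references must
therefore be screened for expression stability in the tissue and
experimental design at hand.

This package implements the standard screening toolbox on Ct tables
with sample metadata: GeNorm, NormFinder, BestKeeper and the
comparative delta-Ct method, a summed *final rank* and a
RefFinder-style geometric-mean consensus across them, selection of the
number of reference genes from GeNorm's pairwise-variation curve, and
delta-delta-Ct relative quantification of target genes with
nonparametric group testing. A seeded synthetic Ct generator emulating
a four-arm trauma study design makes every stage testable without
external data.

## Data model

A `CtMatrix` (an S4 extension of `SummarizedExperiment`) stores one Ct
value per gene and sample, per-sample metadata (`group`, optionally
`tissue` and `timepoint`) and a per-gene role flag
(`candidate_reference` or `target`). Validity requires Ct strictly
inside (0, 50) cycles — the range of standard 40–45-cycle instruments
with headroom — at least 2 genes and 3 samples, unique identifiers and
non-empty group labels. Ct above 35 cycles triggers a low-expression
warning but is not rejected. Cp (crossing-point) values are the same
quantity and are used unchanged. The data model stores one Ct per
(gene, sample); technical replicates are assumed to have been averaged
upstream.

All stability statistics operate on *complete cases* over the gene
panel in use (`completeCases()` drops samples with any missing panel
value and reports them). Pairwise-complete analysis would be unsound
here: the BestKeeper index and the GeNorm normalization factors are
per-sample products over the whole panel.

## The four stability methods

**GeNorm.** Ct values are first transformed to relative quantities
$Q = E^{(\min \mathrm{Ct} - \mathrm{Ct})}$, with amplification
efficiency $E = 2$ by default (perfect doubling; the package exposes
$E$ as a parameter over [1.6, 2.2] but performs no dilution-series
efficiency estimation). For genes $j, k$ the pairwise variation
$V_{jk}$ is the standard deviation over samples of
$\log_2(Q_j/Q_k)$, and the stability value
$M_j = \mathrm{mean}_{k \neq j} V_{jk}$. A truly stable pair has a
constant expression ratio and $M \to 0$. `geNorm()` repeats the
computation with stepwise exclusion of the highest-M gene until two
genes remain; those two share one final M (their pairwise $V$) and tie
at the top of the ranking. Both the M at each gene's exclusion step
(`M_final`) and the single-pass full-panel M are reported, because
published tables do not always state which variant they show.
Suitability is flagged against $M < 1.5$ for heterogeneous sample
panels, or $M < 0.5$ for homogeneous ones.

`pairwiseVariation()` answers "how many reference genes are enough":
with normalization factors $NF_n$ (per-sample geometric mean of the
$n$ most stable genes' quantities), $V_{n/n+1}$ is the SD over samples
of $\log_2(NF_n/NF_{n+1})$; the optimal count is the smallest $n$ with
$V_{n/n+1}$ below the conventional cutoff 0.15. The comparison is
strict (<) on unrounded values; since published analyses have accepted
values printed as exactly 0.15 (plausibly a rounding artifact), a
`cutoffInclusive` option admits equality. If no $n$ passes, the full
panel size is returned with a warning rather than silently picking a
count.

**NormFinder.** A model-based decomposition: within each group, a
two-way (gene x sample) fit yields residual intra-group variances
$s^2_{ig}$ (with an $L/(L-1)$ correction for the sum-to-zero
constraint across the $L$ genes, floored at zero) and inter-group
deviations $\hat d_{ig}$ of each gene's group mean from the group
grand mean (after centering each gene globally). A common inter-group
variance $\hat\gamma^2$ is estimated by method of moments with
$G(L-1)$ effective degrees of freedom, the deviations are shrunk by
$\hat\gamma^2/(\hat\gamma^2 + v_{ig})$ where $v_{ig}$ is the sampling
variance of $\hat d_{ig}$, and the stability value combines bias and
noise:
$\mathrm{sv}_i = \mathrm{mean}_g\,[\,|\tilde d_{ig}| +
\sqrt{\hat\gamma^2 v_{ig}/(\hat\gamma^2 + v_{ig})}\,]$.
If $\hat\gamma^2 = 0$ (no detectable group signal) all sv collapse to
zero and the ranking falls back to the mean sampling SD, with a
warning. With one group (`grouped = FALSE`) sv reduces to the gene's
residual SD from the two-way fit. Ct enters directly as log2-scale
expression without a sign flip: every statistic depends only on
variances and centered deviations, which are sign-invariant.
Bit-for-bit parity with the original spreadsheet macro is not claimed
— its exact small-sample conventions are not recoverable — so the
contract is the estimator stated here plus the property suite (zero on
noise-free data, invariances, oracle agreement of the variance
components, recovery of planted dysregulation). A practical
consequence of the two-way fit is that a little noise is shared across
genes, so with small $n$ the ungrouped sv reliably flags the noisiest
gene but does not resolve fine noise differences between quiet genes.

`interGroupVariation()` exports $\hat d_{ig}$ and the intra-group SD
per gene and group — the numbers behind the usual diagnostic bar plot
that localizes *which* group drives a gene's instability.

**BestKeeper.** Descriptive screening: the per-sample index is the
geometric mean of the candidate genes' Ct; each gene is summarized by
its Ct dispersion (sample SD about the arithmetic mean, and CV as a
percentage) and its Pearson correlation $r$ with the index (p-value
from the t distribution on $n-2$ df). High $r$ and low SD indicate
stability; both rankings are kept separate because the method itself
does not define a single order. A zero-variance gene has undefined
$r$: it is flagged and ranked after all defined-$r$ genes,
deterministically by input order. Because the original tool's
"SD [± Cp]" has also circulated as a mean absolute deviation about the
geometric mean, `sdVariant = "mad-geomean"` provides that variant; the
plain sample SD is the default.

**Comparative delta-Ct.** For gene $i$, the mean over partner genes of
the SD of the pairwise Ct difference. At $E = 2$ this is algebraically
identical to GeNorm's full-panel M; the package computes it
independently from raw Ct and the identity is verified to 1e-12 in the
tests — a deliberate dual-route consistency check.

## Consensus and recommendation

`assembleRanks()` collects fractional (average-on-ties) ranks per
method; BestKeeper contributes its correlation and dispersion rankings
as two columns, matching the two statistics such studies print. The
summed **final rank** adds the NormFinder, GeNorm and both BestKeeper
columns by default (whether published sums used one or two BestKeeper
ranks is typically unstated; the method set is configurable). The
**RefFinder-style** score is the geometric mean of the delta-Ct,
NormFinder, GeNorm and one BestKeeper rank — the dispersion ranking by
default, and GeNorm's exclusion-order ranking — configurable and
labelled "-style" because the web tool's internal conventions are
undocumented. `recommendGenes()` returns the top `optimal_n` genes by
final rank (ties broken by RefFinder-style score, then input order);
genes failing the GeNorm suitability threshold are reported with a
warning but not dropped, mirroring how published tables retain them.

```{r pipeline}
ct <- generateCt(designPreset("paper_d3_bone"), seed = 42)
ev <- evaluateStability(ct)
ev
```

## Target-gene normalization

`normalizeDdct()` implements delta-delta-Ct:
$\Delta Ct = Ct_{target} - \overline{Ct}_{refs}$ per sample,
$\Delta\Delta Ct$ centered on the arithmetic mean of the control
group's $\Delta Ct$, and relative quantity
$rq = E^{-\Delta\Delta Ct}$. Averaging reference Ct arithmetically
equals taking the geometric mean of reference quantities at fixed
efficiency, and the mean-centering makes the control group's geometric
mean rq exactly 1 — an identity the tests verify to 1e-12 on arbitrary
input. The phrase "normalized per individual reference genes" admits a
second reading — normalize to each reference separately, then average
the expressions — so `aggregate = "perReference"` implements that too
(arithmetic mean of per-reference rq); the two coincide on noise-free
data and the Ct-averaging variant is the default.

Group comparisons use the two-sided Mann–Whitney U test
(`mannWhitneyU()`: $U = \min(U_a, U_b)$; exact enumeration p-value
when both groups have at most 8 tie-free observations, otherwise the
normal approximation with tie and continuity correction), each
non-control group against the control group at p < 0.05 without
multiple-testing correction by default — the convention of per-group
contrasts in this field — with Holm/Bonferroni available. A
Shapiro–Wilk gate (`shapiroWilkGate()`) annotates normality but the
pipeline always proceeds nonparametrically; a constant sample returns
a flagged undefined W rather than an error.
`compareHousekeeping()` runs the same target against several reference
sets side by side, the workflow that exposes false positives from
normalizing to a regulated gene and false negatives from a noisy one.

## The synthetic generator

`generateCt()` draws
$Ct_{is} = \mathrm{baseline}_i + \mathrm{shift}_s +
\mathrm{effect}_{i,g(s)} + \varepsilon_{is}$ with a per-sample global
shift shared across genes (technical/RNA-input variability — exactly
the structure normalization must cancel, and which the invariance
tests exploit), independent Gaussian gene-level noise on the Ct scale,
and optional completely-at-random masking. Given a seed the output is
bit-identical across platforms (Mersenne-Twister with inversion
sampling, fixed explicitly).

The presets encode a four-arm trauma design (control, isolated femoral
fracture Fx, traumatic brain injury TBI, combined TBI+Fx; n = 6 per
group) with five to ten murine candidate references. `paper_d3_bone`
plants an *Actb*-like gene shifted by 1.5 cycles in the
fracture-bearing groups over 0.3-cycle noise; `paper_d3_hypothalamus`
plants a *B2m*-like gene shifted in the TBI-bearing groups;
`paper_wat` plants a mildly unstable *Gapdh*-like gene among ten
candidates; `neutral` has no planted effects at 0.1-cycle noise.
Baselines (15–30 cycles), noise (0.1–0.35 cycles) and shifts (0.5–1.5
cycles) are stylized to the scale of typical rodent-tissue RT-qPCR
panels, not fitted to any dataset. The generator deliberately omits
amplification-efficiency differences between genes, plate/batch
effects, non-Gaussian outliers and informative missingness — so
passing recovery tests demonstrates correctness of the statistics
under their own model assumptions, not robustness on real instrument
exports.

## Numerical choices and conventions

* Standard deviations use the $n-1$ denominator throughout; the
  original spreadsheet tools' conventions are not recoverable, so the
  statistical default is used and stated.
* GeNorm exclusion ties break by input gene order; all rank ties take
  fractional average ranks, keeping rank sums scale-free.
* Relative quantities are scaled to the per-gene minimum Ct (highest
  expressor = 1). M is invariant to this choice; NF and V are
  invariant up to constant factors that cancel in log-ratios.
* Negative variance estimates (NormFinder) are floored at zero;
  undefined correlations (BestKeeper) are flagged, not raised.
* File round-trips are bit-exact: Ct values are written with the
  shortest decimal representation that re-parses to the identical
  double.

## Problem sizes in the test suite

The property and recovery tests run at the scale of the emulated
design: 4 groups x 6 samples with 5-gene panels, 100 random matrices
(4–8 genes x 6–30 samples) for oracle-agreement checks, 200 seeded
simulations for each recovery rate, an exhaustive enumeration check of
the exact Mann–Whitney p for all group sizes up to 7, and 2000 null
simulations for its type-I error. These sizes give stable rates
(binomial SE below 2 percentage points) while keeping the whole suite
fast.

## Limitations

The package screens *candidate* references; it cannot conjure a stable
gene where none was measured, and a panel that is uniformly regulated
in the same direction is undetectable by design (all methods work on
relative behaviour within the panel). Stability conclusions are
specific to the tissue, time point and contrast analysed — the
per-condition re-analysis tools (`subsetCt()`) exist precisely because
a gene can be the most stable reference in intact tissue and the worst
in injured tissue. No inter-run calibration, plate-layout handling or
efficiency estimation is provided.
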