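---
title: "Tracing EMT signatures to the tumor stroma: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing EMT signatures to the tumor stroma: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical machinery in `cafsig`, the
assumptions behind it, the parameters that matter, what the synthetic-data
generators do and do not emulate, and the design decisions taken where the
underlying methodology left the choice open.

## 1. Bulk signature scoring

A signature score for sample *s* and gene set *G* is

> score(s, G) = median over g in G of z(g, s),

where z(g, s) is the expression of gene *g* z-scored *within the sample's
tumor type* (group mean subtracted, divided by the group sample standard
deviation with the n−1 denominator). Z-scoring within tumor type removes
lineage-level expression differences; the median makes the score robust to
a few outlying set members.

Choices pinned here so results are bit-reproducible:

* **Zero-variance genes** are set to z = 0 and flagged rather than dropped.
  Dropping them would change the median's argument set discontinuously
  between cohorts; keeping them at 0 (the group mean) is neutral.
* **Even-sized medians** are the mean of the two central values.
* **Missing values** are excluded per sample from the median (with the
  intersection size recorded as `n_genes_used`) and pairwise in
  correlations. The methodology we reimplement is silent here; these are
  the conservative defaults.
* Whether expression should be log-transformed before z-scoring is left to
  the caller: the pipeline scores the values it is given.

Correlation panels report Pearson's r per (tumor type × signature ×
target), with the two-sided p from the t transform on n − 2 degrees of
freedom. Groups with fewer than 3 complete pairs, or constant score
vectors, are omitted with a warning rather than an error, since panels
span many strata of uneven size.

## 2. Dual-species xenograft analysis

In a PDX, stroma is mouse and parenchyma is human, so the per-gene,
per-sample *mouse fraction* f = m/(m + h) measures the stromal share of a
gene's transcripts; f = 0.5 is the equal-contribution reference. Cells with
m + h = 0 are undefined and treated as missing throughout (genes missing
everywhere are excluded and reported). Because overall mouse content
varies between grafts, f is centred within each sample (subtract the
sample mean over genes) before genes are compared; genes are then ranked
by the median adjusted fraction across samples, rank 1 = most stromal.
Median ties get lexicographic order by gene identifier — a deterministic,
documented tie rule matters because the ranking feeds a rank-based test.

**Preranked enrichment.** Stromal enrichment of a set of k genes in a
ranking of n is the classic running-sum statistic: walking down the
ranking, add w_g / W at set members (w_g = |statistic|^weight, W their
sum) and subtract 1/(n − k) otherwise; the enrichment score ES is the
signed maximum deviation, in [−1, 1]. The default `weight = 0` gives the
Kolmogorov–Smirnov-like walk: the input here is a rank list derived from
medians, not a signed differential-expression statistic, so magnitude
weighting has no natural scale (the weighting used by the original
analysis is unstated; `weight` is exposed). On an exact tie between the
positive and negative extremes the positive one is reported — an
arbitrary but fixed convention shared by the test oracles.

**Permutation null and p-value.** The statistic consumes only the
ranking, so the null permutes gene labels: k positions are re-drawn
uniformly, `n_perm` times (default 1000), from a fixed seed. Following
the standard GSEA convention, the observed ES is compared against the
*same-signed* side of the null only:

> p = (1 + #{null ES same sign, at least as extreme}) / (1 + #{null ES same sign}).

An alternative that is sometimes written down — counting sign-directed
exceedances over *all* permutations — looks one-sided but is effectively
two-sided: under the null, P(p < 0.05) comes out near 0.10, because a
random set lands on either side of zero with probability ~1/2 and each
side then contributes its own 5%. We measured exactly this (~0.09–0.14
across seeds) before adopting the sign-conditional form, under which the
delta = 0 calibration test in the acceptance suite measures ~5% as it
should. The +1 terms are the standard bias guard against zero p-values.
NES divides ES by the mean |null ES| of matching sign. For small
choose(n, k) an `exact = TRUE` mode enumerates every placement, and the
test suite checks it against an independently coded full-cumsum walk.

A set spanning the entire ranking has no misses to decrement and is
returned as degenerate rather than scored. BH q-values are computed
within each tumor type across its tested sets (step-up with monotone
enforcement), matching the per-type FDR control of the original design.

## 3. Sentinel mutual-rank expansion

For genes a, b, let rank_a(b) be b's 1-based position in a's neighbor
list ordered by descending signed Pearson correlation (self excluded,
correlation ties broken by gene id). The mutual rank

> MR(a, b) = sqrt(rank_a(b) × rank_b(a))

is symmetric and ≥ 1, with reciprocal top neighbors at exactly 1.
`sentinel_expansion` returns all genes with MR ≤ `mr_cutoff` (default 5),
ascending, ties broken by larger |correlation| then gene id, truncated to
`max_genes` (default 25). Signed rather than absolute correlation is used
deliberately: cell-type markers of interest are *positively* co-expressed
with the sentinel. The published derivation that reduced the CAF sentinel
FAP to {COL1A1, COL1A2, COL3A1} calls its threshold only "stringent", so
the cutoff here is explicit and overridable, and the packaged 3-gene CAF
set is shipped as a fixture (`caf_signature()`), not re-derived. Across
cohorts, genes are aggregated by their median MR over the cohorts in
which both gene and sentinel are usable — robust, and a gene co-expressed
in only a minority of cohorts is excluded, which is the intended
stringency.

One property worth knowing: with an unstructured (i.i.d. noise)
background, a background gene occasionally has the sentinel as its
reciprocal top-ranked neighbor purely by chance despite a small
correlation, and mutual rank (correctly, per its definition) admits it.
Real transcriptomes are modular, which suppresses this; the test fixtures
therefore give background genes their own co-expression modules.

## 4. Single-cell stage

QC keeps a cell iff nFeature > 200 and nFeature < 6000 and mitochondrial
fraction < 0.15 and nCount < 15,000 — all four bounds strict, so a cell at
exactly 200 detected genes is rejected. The per-cell score is the *mean*
normalized expression over set genes (not the median: single-cell
sparsity makes per-cell medians mostly zero), min–max rescaled to 0–100
over all cells in the dataset; an all-constant raw score maps to 0 with a
degenerate flag. Fold enrichment per cell type is the type mean divided
by the grand mean. The 0–100 scaling and the per-cell scoring function
behind the original figures are not described; these are this package's
explicit choices.

The fibroblast-vs-parenchyma comparison defaults to the unpaired
rank-sum (Mann–Whitney) test, because the compared cell populations are
unpaired; the originally named signed-rank test is provided for genuinely
paired designs (e.g. per-patient medians) but the intended pairing was
not stated, so no pairing is guessed. p-values are exact — full
enumeration over placements (rank-sum) or sign flips (signed-rank), with
midranks for ties — whenever both groups have ≤ 10 observations, and use
the normal approximation with tie correction otherwise. Mitochondrial
genes are recognized by a configurable prefix upstream of this package's
inputs; QC metrics arrive as data.

## 5. Survival association

For each tumor type and signature, overall survival is modeled by a
univariate Cox proportional-hazards regression on the score, assuming a
linear effect. The partial likelihood is maximized by Newton–Raphson with
step-halving to |Δ log L| < 1e−9 (max 50 iterations, failure is an error
with diagnostics); the standard error comes from the observed
information. Tied event times use Breslow's approximation by default —
the simplest deterministic choice, with Efron available — and the fit is
tested against both a hand-coded grid-search oracle and an independent
reference implementation. Hazard ratios are reported per interquartile
range of the observed scores, HR_IQR = exp(β·IQR), with Wald 95%
confidence intervals; quantiles use linear interpolation between order
statistics (R type 7), pinned so tests are bit-exact. HR_IQR is invariant
to affine rescaling of scores (β scales down as IQR scales up), which the
suite asserts exactly. No covariate adjustment is performed: the
association machinery is deliberately univariate, so estimates are
prognostic associations, not causal or adjusted effects.

## 6. Synthetic data: what a green test establishes

The generators produce the *assumed* statistical structure with known
truth, each bit-reproducible from an explicit seed (the caller's RNG
stream is saved and restored):

* **Bulk mixtures** (default 1000 genes × 100 samples): purity ~
  Beta(5, 2) — tumors mostly malignant with variable stromal admixture;
  a 50-gene stromal block at baseline + 2·(1 − purity), a 50-gene
  epithelial block at baseline + 2·purity, everything else N(0, 1) noise
  around baseline 5. Effect 2 against noise 1 makes single genes weak
  purity correlates but 50-gene median scores strong ones (r ≈ ±0.9),
  which is the regime the bulk analysis assumes.
* **Xenograft counts** (default 2000 genes × 60 samples): totals
  Poisson(depth · Gamma(2, 2) rate, depth 50); per-sample base mouse
  probability Beta(6, 14) (mean 0.3); planted genes' probability shifted
  by +0.15 (stromal) or negative (parenchymal analogue), clamped to
  [0.01, 0.99]; mouse counts Binomial given totals.
* **Single cells** (default 4 types × 200 cells, 1000 genes): negative
  binomial counts (lognormal gene means, size 2), 30% dropout, a 30-gene
  signature multiplied ×3 in fibroblasts; log1p CP10K normalization; QC
  metrics computed from the counts with mito fractions Beta(2, 28), plus
  20 contaminant cells cycling through the attainable threshold
  violations (too few features, high mito, excessive counts — the
  nFeature < 6000 bound cannot be crossed with a 1000-gene space).
* **Survival**: event times Exponential(0.1 · exp(β·score)), independent
  Exponential(0.05) censoring (≈ 2/3 of subjects observed to event at
  β = 0.5 with standard-normal scores).

These fixtures carry none of the things that make real data hard: no
batch effects, no ambient RNA or doublets, no purity-estimation error, no
correlated gene–gene noise beyond the planted blocks, no informative
censoring. A green acceptance suite therefore establishes that the
*machinery* is correct and calibrated on data satisfying its assumptions
— recovery of planted structure, nominal type-I error, estimator
consistency — not that any biological conclusion transfers to a new
cohort.

## 7. Known limitations

* The preranked null treats genes as exchangeable; genes with few
  informative samples have noisier median fractions, which a gene-label
  permutation ignores (set-level q-values on very sparse genes should be
  read cautiously).
* The mutual-rank cutoff that reduces a sentinel's neighborhood to a
  handful of genes is data- and cohort-dependent; defaults are starting
  points, not recommendations.
* Cox fits are univariate by design; confounding between signature
  scores and other prognostic variables is out of scope.
* The 0–100 single-cell score is dataset-relative (min–max), so scores
  are not comparable across datasets without joint rescaling.
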