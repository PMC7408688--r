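---
title: "Methods: growth classification, signature extraction and survival screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: growth classification, signature extraction and survival screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainsig)
```

This vignette documents the models behind `brainsig`, the parameters that
matter, the design choices made where the procedure was genuinely open,
and the limits of what the package's simulations establish.

## The analysis in outline

The pipeline mirrors a three-stage study of brain colonization in
HER2-positive breast cancer cell lines:

1. nine cell lines are injected intracranially into mice and imaged every
   seven days; each line is summarized by its day-28 bioluminescence
   growth ratio and the panel is split into a rapid-growth group
   (RG = UACC-893 and MDA-MB-453) and a medium-to-slow-growth group
   (MSG, the other seven lines);
2. a log2 expression matrix over the nine lines is filtered for genes
   that are consistently and distinctively extreme in the RG pair — the
   brain-colonization signature;
3. signature genes are screened for association with patient survival in
   a high/low expression dichotomy.

## Growth kinetics

Radiance is treated as given (no image processing). For mouse *m*,
`ratio(t) = radiance(t) / radiance(0)`; day 0 must be present and all
radiance positive. The per-line summary is
`log10(mean over mice of ratio(day))` with `day = 28` by default — the
day is a parameter because endpoints in such experiments often run
longer. Mice within a line are aggregated by the arithmetic mean of
ratios before the log (the "mean normalized radiance" convention); a
geometric-mean option is provided for users who prefer averaging on the
log scale. Unequal mouse counts per line (3 vs 4) are handled by the
plain mean, with no weighting.

Classification is deliberately parameter-free by default: the published
split is visually obvious but no numeric cutoff is stated, so `max_gap`
sorts the summaries, splits at the largest gap, and reports the gap
midpoint as the threshold it used. This is reproducible, invariant to
adding a constant to all summaries, and errs loudly (a degenerate-input
error) when all summaries are equal. A `fixed_threshold` mode is
available when an external cutoff is preferred. Correlation of in vivo
growth with in vitro growth (`log2(N(4)/N0)`, `N0 = 1.5e5` seeded cells)
or with a log10 marker band intensity uses Pearson correlation on the
already-log-transformed quantities; the p-value is reported but not
thresholded, because the correlation is descriptive in this design.

## Signature extraction

All fold-changes are differences of log2 values; inputs are assumed
already log2-transformed and normalized (the upstream microarray
preprocessing is out of scope, so the reader validates finiteness only).
Z-scores are computed per gene across all nine samples jointly, with the
sample (n−1) standard deviation; a population-sd option exists. Constant
genes map to z ≡ 0 and their count is reported, rather than producing
NaNs.

Three per-gene statistics feed the filter:

* `rg_z` — the mean of the two RG samples' z-scores. The criteria use a
  single scalar "RG z-score" per gene; the group mean is the minimal
  reading, and a stricter `rgZMode = "each"` (both RG samples must pass)
  is shipped for sensitivity analysis. The strict mode can only shrink
  the sets, which the tests verify.
* `rg_logfc` — MDA-MB-453 minus UACC-893. The orientation is fixed for
  reporting; the criterion `|rg_logfc| < cut` is symmetric, so it does
  not affect membership.
* `rg_msg_logfc` — RG mean minus MSG mean.

The up set is `{−c < rg_logfc < c, rg_msg_logfc > f, rg_z > z}` with all
thresholds defaulting to 1.0 and all inequalities strict, exactly as the
criteria are printed; the down set mirrors it. Strictness matters only
on a measure-zero boundary for continuous data but is part of the
contract: a gene with `rg_z` exactly 1.0 is excluded. The four Venn sets
use the same conventions. Negating the matrix swaps up and down exactly
(every criterion is odd under negation), raising `zCut`/`rgMsgCut` can
only remove genes, and raising `rgConsistencyCut` can only add them —
these invariants are enforced by property tests over random matrices.

Whether the published signature entries are probes or collapsed genes is
ambiguous in the source material, so the container records its `level`
(`probe`/`gene`) explicitly and `collapseProbes()` supports both common
conventions — `max_mean` (keep the probe with the highest mean
expression; the default, as in most microarray pipelines) and `mean` —
letting the user run the filter at either level.

Row ordering of the signature heatmap is reproduced by agglomerative
clustering of the z-score rows with complete linkage and Euclidean
distance (the defaults of the heatmap package the original analysis
used); average linkage and correlation distance are options. Columns are
never clustered: samples stay in fixed group order, RG first. Ties are
broken by input order and the leaf order follows the standard
left-before-right merge convention, so the output is deterministic.

## Survival screening

The screen reproduces the structure of a signature-gene survival table:
per gene, a high/low dichotomy, a two-sample log-rank p-value, and the
mean survival of each group.

* **Estimator.** Kaplan–Meier product-limit curves via the `survival`
  package, with Greenwood variance and 95% pointwise CIs on the
  log(−log) scale, clipped to [0, 1]; where the transform is undefined
  (S = 0 or 1) the bounds collapse to the point value. Subjects censored
  at an event time remain at risk at that time.
* **Test.** The standard two-sample log-rank test
  (`(ΣO − ΣE)² / ΣV` against χ²(1)); the source material names no test,
  and log-rank is the standard KM companion. Zero events or zero
  variance raise errors rather than returning NaN.
* **Mean survival.** Under right censoring an unrestricted mean is
  undefined, so "mean survival" is the restricted mean survival time:
  the area under the KM step function up to a horizon, shared across
  groups and defaulting to the largest observed time in the pooled
  cohort.
* **Dichotomization.** The published per-gene group sizes are unequal
  and gene-specific, which no single fixed split can produce, so the
  default scans cuts on the 0.10–0.90 expression-quantile grid (step
  0.05) and picks the cut minimizing the log-rank p-value. This is an
  optimistic, selection-biased procedure; the result carries a
  `selection_inflated` flag and the full scan, and median and z-score
  cuts are available when honest p-values are needed.
* **Multiplicity.** Raw p-values drive the adverse-high/adverse-low
  flags (mirroring a table that reports raw p only); BH q-values are
  emitted alongside. Per-gene failures (constant expression, degenerate
  splits) are warnings that skip the gene, never fatal.

## Synthetic data

The simulators generate inputs with exactly the statistical structure
the analysis assumes — which is what makes the test suite's claims
precise, and also bounds what they mean.

**Expression.** Per-gene baselines are uniform on [4, 12] (log2 scale);
the seven MSG lines get independent Gaussian noise (`noiseSd = 0.3`);
planted genes shift both RG samples by ±`effectDelta` (default 2.5).
The two RG samples are modeled as replicate measurements of a shared
rapid-growth expression state, each with small independent jitter
(`rgInconsistencySd = 0.1`). This is a deliberate design choice: the
filter's defining property is that it recovers genes whose RG pair is
*consistent* (within-pair logFC inside ±1) and *distinct* (pair-vs-rest
logFC above 1), so the generator separates the two dispersions it is
designed to distinguish — the within-pair replicate jitter and the
between-line biological noise. Under these defaults the planted sets are
recovered exactly (direction-aware F1 = 1.0 across seeds) and null
matrices yield essentially no calls; if instead each RG sample carried
the full independent 0.3-sd biological noise, the within-pair logFC
(sd ≈ 0.42) would spill past the ±1 consistency bound for a few percent
of planted genes and exact recovery would be impossible for any filter
with these thresholds — a property of the data model, not of the
implementation. Samples are named after the nine cell lines so fixtures
exercise the real group-assignment path.

**Growth.** `radiance(t) = radiance0 · 2^(t/doublingTime) · exp(ε)` with
lognormal noise `ε ~ N(0, σ)`, `σ = sqrt(log(1 + CV²))`, applied at day 0
too. Defaults: RG doubling 3.5 days, MSG 14 days, CV 0.2, three mice per
line, measurements every 7 days to day 28 — a clearly bimodal panel, as
in the study this emulates.

**Survival.** Expression is standard normal per gene; event times are
exponential with rate `baselineHazard · exp(Σ β_g x_g)` (proportional
hazards by construction), censoring is exponential truncated at an
administrative horizon. Defaults (`baselineHazard = 0.01`/month, median
≈ 69 months; `censoringRate = 0.004`; horizon 300 months) give roughly a
quarter of records censored, a plausible regime for a large breast-cancer
cohort.

Every simulator takes a `seed`, is bitwise reproducible under it, and
restores the caller's RNG state. What the simulations do **not**
establish: performance on real microarray data (probe effects, batch
structure, correlated genes, non-Gaussian noise), non-proportional
hazards, informative censoring, or the behavior of the optimal-cut
dichotomy's p-values as confirmatory statistics.

## Numerical and interface choices

* Expression TSVs are written with 17 significant digits so read/write
  round trips are bit-exact; "." decimal, no quoting.
* Degenerate inputs error early and specifically: missing day-0,
  non-positive radiance, duplicate ids (with coordinates for
  non-numeric cells), single-sample z-scores, one-sample RG groups,
  constant expression in a dichotomy, all-equal growth summaries under
  `max_gap`.
* `runPipeline()` output is a pure function of (inputs, config, seed):
  the results bundle (`results.json`, TSV/GMT/CSV files) contains no
  timestamps and is byte-identical across repeated runs; wall-clock
  times go to `run.log` only. On stage failure, partial outputs are
  removed and the error is re-thrown tagged with the stage name.

## Problem sizes in the test suite

The suite validates each operation against independent oracles
(per-gene loops, exhaustive predicate evaluation, hand-computed
product-limit tables, an O(n³) agglomeration, closed-form exponential
survivor functions) on deliberately modest problem sizes: 500 × 9
matrices for the filter oracles (20 seeds), 2000-gene planted recovery
(20 seeds), 100-instance property sweeps for anti-symmetry and
monotonicity, 2000 null cohorts of n = 200 for log-rank calibration,
100 cohorts of n = 400 for screen power, 1000 cohorts of n = 200 for
Greenwood CI coverage, and 50 seeds of nine-line growth panels. These
sizes give tight Monte-Carlo error on the calibration checks while the
whole suite runs in well under a minute.

## Known limitations

* The package analyzes expression matrices as given; it performs no
  microarray preprocessing, annotation lookup, or batch correction.
* The signature filter is a deterministic threshold rule with no
  significance testing — by design, faithful to the procedure it
  implements; users wanting error control should treat the sets as
  hypothesis-generating.
* The optimal-logrank dichotomy's p-values are exploratory; the package
  flags but does not correct the selection.
* Which survival endpoint (overall vs disease-specific) the original
  cohort analysis used is unknowable from the source; the simulated
  cohorts model a single generic endpoint.
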