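# brainsig

Roughly 30% of HER2-positive breast cancers metastasize to the brain, yet
most experimental work on breast-cancer brain metastasis has relied on
triple-negative cell lines. One way to study the HER2-positive case is to
inject a panel of HER2-positive cell lines intracranially into
immunodeficient mice, follow each tumor by bioluminescence imaging, split
the panel into a rapid-growth group (RG) and a medium-to-slow-growth group
(MSG), and ask which genes the RG lines share — a brain-colonization
expression signature — and whether those genes also stratify patient
survival.

`brainsig` implements that analysis as a tested, reusable R pipeline for
computational biologists working with cell-line panels: growth
quantification and classification, signature extraction, and survival
screening, plus seeded simulators so every stage can be exercised and
validated without access to the original microarray or patient data.

## The method

**Growth kinetics.** Each mouse's radiance series is normalized to its
day-0 value, giving a growth ratio `R(t) = radiance(t) / radiance(0)`.
A cell line's in vivo growth is `log10(mean_mice R(28))`, and lines are
split into RG vs MSG at the largest gap in the sorted summaries (the cut
is parameter-free and reported; a fixed threshold is also available).

**Signature extraction.** With log2 expression `x_gs` for gene *g* in
sample *s*, each gene is standardized across the nine samples,
`z_gs = (x_gs − mean_g) / sd_g`, and three per-gene statistics are formed:

* the RG z-score: the mean of `z` over the two RG samples (a strict
  "each sample" mode is available);
* the within-RG consistency logFC: `x_{g,MDA-MB-453} − x_{g,UACC-893}`;
* the RG−MSG logFC: mean log2 expression in RG minus mean in MSG.

A gene is an **up** signature gene when (strict inequalities throughout)

```
−1 < rg_logfc < 1   and   rg_msg_logfc > 1   and   rg_z > 1
```

and a **down** signature gene under the mirrored conditions. Four Venn
partition sets (`rg_up`, `rg_down`, `msg_up`, `msg_down`) and a
hierarchical clustering of the signature rows (complete linkage,
Euclidean distance on z-scores) reproduce the structure of the published
Venn diagrams and heatmap ordering.

**Survival screening.** For each signature gene, patients are
dichotomized into high/low expression (default: the cut on a 0.10–0.90
quantile grid minimizing the log-rank p-value — the scan is returned and
flagged, since selecting the cut inflates type-I error; median and
z-score cuts are available). Groups are compared with the two-sample
log-rank test, Kaplan–Meier curves carry Greenwood-variance log(−log)
95% CIs, and "mean survival" is the restricted mean survival time (area
under the KM curve to a common horizon). Genes with `p < α` are flagged
`adverse-high` or `adverse-low` by which group survives shorter;
Benjamini–Hochberg q-values are reported alongside the raw p-values.

## Worked example

```r
library(brainsig)

## planted-signature expression matrix: 2000 genes, 40 up, 40 down
sim <- simulateExpression(seed = 1)
sig <- extractSignature(computeGeneStats(sim$expression))
sig
#> BrainSignature: 40 up / 40 down (80 features)
#>   Venn sets: rg_up=69, rg_down=59, msg_up=0, msg_down=0
#>   thresholds: z > 1, |RG consistency logFC| < 1, |RG-MSG logFC| > 1 (RG z mode: mean)

setequal(signatureUp(sig), sim$truth$up)   # planted genes recovered exactly
#> [1] TRUE

## growth classification from simulated radiance series
bl <- simulateBioluminescence(seed = 1)
classifyGrowth(summarizeGrowth(growthRatio(bl$series), day = 28))
#> GrowthClassification (max_gap, threshold = 1.54037):
#>   RG: MDA-MB-453, UACC-893
#>   MSG: BT-474, HCC-1419, HCC-202, HCC-2218, MDA-MB-361, UACC-812, ZR-75-1

## survival screen on a simulated proportional-hazards cohort
co <- simulateCohort(nPatients = 400, beta = c(TM4SF1 = 0.7, CSTA = 0), seed = 1)
survivalScreen(co$cohort, c("TM4SF1", "CSTA"), strategy = "median")
#>     gene n_high n_low      cut   p_value   q_value high_mean low_mean         flag
#> 1 TM4SF1    200   200 -0.02664 1.128e-15 2.256e-15     64.65    152.1 adverse-high
#> 2   CSTA    200   200 -0.11062 7.669e-01 7.669e-01    104.87    113.1           ns
```

The signature object reports 40 up / 40 down genes — exactly the planted
sets. The classifier recovers the two rapid-growth lines with the
max-gap threshold it used (log10 ratio 1.54). In the screen, the gene
with a planted log hazard ratio of 0.7 per SD is flagged `adverse-high`
(its high-expression group's restricted mean survival, 64.7 months, is
far below the low group's 152.1), while the null gene is not flagged.

`runPipeline(config)` chains the stages from a flat YAML/list config and
writes a deterministic results bundle (TSV/GMT/CSV plus `results.json`).

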