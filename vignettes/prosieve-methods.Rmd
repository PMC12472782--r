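---
title: "Methods: differential-abundance screening with prosieve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential-abundance screening with prosieve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prosieve)
```

## The problem

Label-free shotgun proteomics of a balanced 2×2 design — genotype (wild type
vs transgenic) crossed with treatment (vehicle vs an insulin-sensitizing
compound), usually with male and female strata — yields a wide table of
protein abundances spanning several orders of magnitude, confounded by
per-sample acquisition depth and contaminated by occasional gross outlier
measurements. `prosieve` implements a complete screening path from that raw
table to a short candidate list: within-group outlier removal, per-sample
normalization, per-protein two-group testing with volcano classification,
variance-ratio candidate ranking with FDR control, and offline
interaction-network and term-enrichment summaries. A companion module solves
the a-priori sample size for the design's interaction contrast, and a
synthetic spike-in generator makes every stage testable end to end.

## Stage by stage

### Outlier QC

For each protein within each experimental group (genotype × treatment,
further split by sex when annotated) we compute, on log10 abundances, each
value's mean absolute distance to its `k` nearest neighbours within the
group (`k = min(3, n - 1)` by default). Before scoring, each sample's median
log level within the group is subtracted: per-sample depth offsets are
shared across proteins, and without this step they both inflate the score
scale and mask genuine single-cell anomalies.

A value is flagged when its score exceeds the protein's median score by more
than `z_threshold` robust standard deviations, where the scale is the MAD of
median-centred scores pooled across *all* proteins of the group. Pooling is
essential: a MAD estimated from the 5–6 values of one protein is far too
unstable to standardize against. The default `z_threshold = 20` was
calibrated by simulating the null (Gaussian multiplicative noise, groups of
5–6, `k = 3`): the robust z of a KNN score is strongly right-skewed — its
clean-data 99th percentile is around 11 and the 99.9th around 18 — so the
familiar value-based cutoff of 3.5 would flag roughly a tenth of perfectly
clean cells. At 20, fewer than ~0.1% of clean cells are flagged while a 10×
gross error scores z ≈ 30–45 and is removed essentially always.

Flagged cells are set to missing, not imputed; downstream means and tests
use the remaining values. Sweeps repeat on the cleaned matrix until a pass
flags nothing (removing extreme cells slightly tightens the pooled scale,
which can expose borderline cells), so the returned matrix is a fixpoint and
re-running the QC changes nothing. Groups with fewer than three available
values are skipped with a warning rather than aborting the run.

### Normalization

Four per-sample scaling schemes are provided: mean-based, total-count,
housekeeping-protein (e.g. beta-actin/beta-tubulin), and the pipeline
default, **down-scaling** — every sample is multiplied by
`min(stratum totals) / own total`, so all totals drop to the stratum
minimum. Factors are computed independently within sex strata when sex is
annotated, and missing (removed) cells are excluded from totals so QC does
not deflate them. Down-scaling factors always lie in (0, 1] with at least
one exact 1 per stratum, and never inflate low-abundance signal.

`evaluate_normalizations()` reports three diagnostics per method (lower is
better): the CV of post-normalization sample totals (residual depth), the
median within-cell CV across proteins (within-group tightness), and the mean
absolute change of the row-centred log2 cross-sample profile relative to raw
over the lowest-abundance quartile. The last criterion — "distortion of the
signal of weakly expressed proteins" — has no standard quantitative
definition; we operationalize it as profile distortion because any
per-sample scaling preserves within-sample composition, so only the
cross-sample profile can be distorted. The pipeline default remains
down-scaling regardless of the table, which is reported for transparency.

By default totals are computed after outlier removal; the stages are plain
functions, so the opposite order is a two-line change if a user prefers it.

### Differential testing and volcano classification

Per protein, the fold change is the ratio of case to control mean abundance,
log2-transformed. Normality of each group is screened with Shapiro–Wilk at
α = 0.05: if both groups pass, the classical equal-variance Student's
t-test is used; otherwise the two-sided Mann–Whitney U test, with the exact
null distribution whenever both groups have at most 8 values and no ties
(at the design's group sizes of 4–12 the normal approximation can be poor)
and the tie/continuity-corrected approximation otherwise. Constant groups —
on which Shapiro–Wilk is undefined — are routed nonparametrically; two
identical constant groups are degenerate and reported with p = 1; groups
with fewer than three values are left untested.

A protein is called **up** when `p < 0.05`, `log2FC > 0.32` and the
arithmetic change `|FC − 1|` is at least 25%; **down** when `p < 0.05`,
`log2FC < −0.41` and the change condition holds. The asymmetric printed
cuts correspond to ±25% on the ratio scale (log2 1.25 ≈ 0.322,
log2 0.75 ≈ −0.415); they are kept as literal constants of the decision
rule and exposed as parameters. Inequalities on p and log2FC are strict. No
multiplicity adjustment is applied at this stage — the unadjusted calls feed
the network exploration, and FDR control is deferred to candidate
selection.

### Candidate selection

Each protein's **relative variance** is the sample variance of its
genotype × treatment cell means (denominator G − 1) divided by the pooled
within-cell sample variance. A zero pooled variance is guarded by
ε = 1e−12 and the ratio capped at 1e12. Proteins in the top 5% of relative
variance are retained — `⌈0.05·m⌉` of the `m` scored proteins, with all
boundary ties included (both the nominal and actual counts are reported) —
and Benjamini–Hochberg adjustment is applied to the retained proteins'
test p-values. BH is used because it is the field default for this kind of
screening; the search-engine stage's Percolator-style FDR concerns spectrum
assignment and is out of scope here.

### Offline network and enrichment

Interaction evidence is read from an exported edge table
(`protein1`, `protein2`, `combined_score` 0–1000); reversed duplicates are
collapsed keeping the maximum score and edges below `min_score = 400` (the
conventional medium-confidence cut) are dropped. The subgraph induced by
the significant proteins is decomposed into connected components; those
with at least 3 members are reported largest-first with deterministic tie
breaks. Term enrichment against local GMT gene sets uses the upper
hypergeometric tail P(X ≥ overlap) with the quantified proteins as the
default universe (overridable) and term sets intersected with it; q-values
and the top-20-by-FDR report are computed within each category (BP/CC/MF/
KEGG are not pooled), since cross-category p-values are not comparable.

### Interaction power

The planning scenario assumes the untreated transgenic cell deviates from
the control mean by a fraction `e` (default 0.35) while treatment restores
it; the treated wild-type cell is assumed unchanged — the minimal assumption
consistent with "treatment normalizes to control". With within-cell SD
`σ = cv × control mean` (default cv 0.20), the 2×2 decomposition gives
interaction effects of ±`e/4` in every cell, Cohen's
`f = (e/4)/σ` (0.4375 at the defaults), and noncentrality
`λ = n·Σ(interaction effects)²/σ²`. Power of the 1-df interaction F-test is
the upper tail of a noncentral `F(1, 4(n−1), λ)` beyond the central-F
critical value at α = 0.05 — the F test is inherently one-tailed; "two-sided
α" refers to the underlying difference-in-differences contrast.
`solve_n()` returns the smallest `n ≥ 2` meeting the target power (0.80),
and `power_design()` adds a one-animal buffer per cell for procedural
losses. A Monte-Carlo companion (`interaction_power_mc()`) simulates the
balanced ANOVA directly and is used as the independent cross-check in the
test suite.

## The synthetic spike-in generator

`simulate_dataset()` draws protein baselines log-uniformly over 4–9 decades
(emulating the coexistence of very high- and very low-abundance proteins),
assigns a fraction of proteins (default 5%) a genotype effect of ±35%
confined to the untreated transgenic cell — half up, half down, so both
volcano tails are exercised — and applies three noise layers: multiplicative
Gaussian within-cell noise with CV 0.20 of the cell mean (redrawn below −1
so abundances stay positive), log-normal per-sample depth multipliers
(log-SD 0.2), and gross 10× outliers in a small fraction of cells (0.5%).
Defaults mirror the planning scenario: 6 samples per genotype × treatment
cell within each sex stratum, i.e. 12 per cell and 48 samples. Every run is
fully determined by its seed and returns the ground truth (spiked flags,
true ratios, injected cells) alongside the matrix.

What the generator does **not** emulate: peptide/spectrum-level structure,
missing-not-at-random censoring of low-abundance proteins,
protein–protein abundance correlation, or sex-specific effect sizes.
Passing recovery tests therefore demonstrate that the pipeline's logic is
correct under its own stated assumptions, not that real tissue data satisfy
those assumptions.

## Validation problem sizes

The test suite validates the pipeline at the scale it was designed for:
recovery runs use 2000 proteins × 48 samples with 100 spiked proteins over
ten seeds (mean directional sensitivity of the volcano call on spiked
proteins at least 0.80, empirical false-discovery proportion at most 0.20),
a matched no-effect condition (up+down call rate at most 2%), outlier
fixtures of 1000 proteins over five seeds (all injected 10× cells flagged,
under 1% of clean cells flagged, removal idempotent), and oracle
equivalence checks (exact Mann–Whitney vs exhaustive label enumeration, BH
vs an independent step-up implementation, hypergeometric tails vs
resampling, analytic power vs Monte-Carlo ANOVA). The injected-outlier
fixtures use a 0.2% injection rate so that injected cells remain a sparse
minority within any 6-cell group; at markedly higher rates a group can
receive three injected cells out of six, a 3–3 split that no outlier
detector can resolve.

## Known limitations

* The KNN outlier screen assumes roughly symmetric within-group noise on
  the log scale; strongly skewed biological subpopulations (e.g. a
  responder/non-responder split) could be flagged as outliers.
* Down-scaling equalizes totals, not distributions; it cannot correct
  intensity-dependent (nonlinear) biases, for which quantile or VSN-type
  methods — deliberately out of scope — would be needed.
* The equal-variance t-test follows the classical form; with strong
  variance heterogeneity between groups its p-values are approximate.
* Relative variance is a one-way criterion over the four design cells; it
  does not isolate the interaction the way the power module's contrast
  does, and a strong main effect alone can rank a protein highly.
* Enrichment p-values are conditional on the provided annotation sets and
  universe; with a non-quantified-background universe they are not
  comparable across experiments.
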