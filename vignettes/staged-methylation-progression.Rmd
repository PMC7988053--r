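---
title: "Staged methylation progression analysis: models and methods"
author: "methylProgression maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staged methylation progression analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylProgression)
```

# The scientific problem

Prostate cancer progresses under treatment pressure through recognizable
states: a castration-sensitive state, castration-resistant disease (CRPC),
enzalutamide-resistant CRPC, and — in the most aggressive trajectory —
treatment-induced neuroendocrine disease (tNEPC). DNA methylation is one of
the most informative molecular layers for telling these states apart.
`methylProgression` implements a complete analysis chain for staged
methylation-array studies of this kind: differential methylation between
stages, set algebra over the stage comparisons, genomic-context composition,
gene-level net methylation scoring, integration with expression changes, and
finally a cell-free DNA (cfDNA) biomarker readout that asks whether a
cell-line-derived methylation signature is visible in patient plasma and
predictive of time to clinical progression (TTP).

Because studies of this design publish their array matrices only as
supplementary material, the package ships a first-class synthetic-data
generator with known planted truth. Every analysis stage therefore has a
recovery surface: sensitivity and false discovery against planted probes,
scenario-label recovery, and cohort-level correlation recovery.

# The beta value and the differential test

Methylation at a CpG is summarized by the beta value
$$\beta = \frac{M}{U + M + 100},$$
where $M$ and $U$ are methylated and unmethylated allele intensities and the
offset 100 regularizes low-intensity probes (`betaFromIntensities()`). Beta
values live in $[0,1]$ and the package's central container, `BetaSet`,
extends `SummarizedExperiment` with that invariant enforced.

Differential methylation between two stages is tested per probe on the beta
scale with an empirical-Bayes moderated t statistic. With only 2–3
replicates per cell line, per-probe variances are noisy; the moderated test
borrows strength across probes by fitting a scaled inverse-chi-square prior
to the per-probe pooled variances (method of moments on the log variances,
with a Newton solve of the trigamma inverse) and shrinking each variance
toward the prior:
$$\tilde s^2_p = \frac{d_0 s_0^2 + d\, s_p^2}{d_0 + d},\qquad
  t_p = \frac{\Delta\beta_p}{\tilde s_p\sqrt{1/n_1 + 1/n_2}},$$
with $d_0$ extra degrees of freedom added to the null t distribution
(capped at the pooled residual degrees of freedom across probes). A plain
Welch t is available as the `method = "welch"` fallback for users who
prefer no shrinkage. Two-sided p values are Benjamini–Hochberg adjusted
across all tested probes, and a probe is a DMP when

* `q < 0.01` (FDR threshold), and
* `|Δβ| ≥ 0.2` (effect-size threshold on the beta scale).

Both thresholds are arguments of `callDMPs()`; 0.01/0.2 are the defaults
used throughout. Testing on the beta scale keeps the effect threshold
directly interpretable; whether M-value testing would behave differently on
heteroscedastic edge probes is a known trade-off, and the variance
shrinkage absorbs most of it in practice. The shrinkage fit is
cross-checked in the test suite against an independent implementation
(limma's `squeezeVar`), including the boundary case of no excess
dispersion, where the prior degrees of freedom are infinite and every probe
shares the arithmetic-mean variance.

Probe filtering (`filterProbes()`) removes SNP-related, cross-reactive and
multi-hit probes, and — when detection p values are supplied — probes
failing detection in any sample (the strictest rule; a failing-fraction
rule is available via `maxFailFraction`). The normalization hook
(`normalizeBeta()`) defaults to the identity: the synthetic data carry no
probe-type intensity bias, so no quantile/type-II correction is applied; a
per-sample transform can be plugged in for real data.

# Comparison-set algebra

A staged design produces a family of comparisons (each line vs the
parental line, resistant lines vs control CRPC, neuroendocrine lines vs the
adenocarcinoma-resistant line; `progressionDesign()` encodes the default
scheme). `commonDMPs()` intersects DMP sets by probe id; a probe is
"common" only if it passed thresholds in *every* member comparison — no
pooling of p values — and, in `same_direction` mode, only if its direction
agrees everywhere. `directionSwitches()` tabulates the 2×2
hyper/hypo quadrants between two stages, separating probes that keep their
trend from those that invert it (the biologically interesting
direction-switch class). `deltaConcordance()` quantifies coherence of
shared probes as the Pearson correlation of their Δβ values.

# Genomic context and gene scores

Probes are annotated (`annotateDMPs()`) with genomic feature (TSS, defined
as 0–1500 bp upstream of a start site; 5'UTR; first exon; body; 3'UTR;
intergenic) and CpG-island context (island; shore, within 2 kb; shelf,
2–4 kb; open sea). `regionComposition()` reports per-region counts and
hyper/hypo fractions, counting each probe once even when it is annotated to
several genes; a grouped variant collapsing 5'UTR/first-exon/3'UTR into one
UTR class is emitted alongside, since published region breakdowns are
ambiguous about that grouping.

Gene-level aggregation (`geneDMPSummary()`) deliberately counts per gene —
a probe serving two genes contributes to both. For genes with at least
`minDmps` DMPs (default 6, the strict reading of "more than 5"; pass 5 for
the inclusive reading), the net methylation score is
$$\mathrm{score} = \log_2\frac{n_{hyper} + 0.5}{n_{hypo} + 0.5},$$
with the pseudocount keeping zero-denominator genes finite and rankable;
`net_class` compares the raw counts. `overlapWithRegions()` intersects DMP
positions with external differentially methylated CpG/region sets (e.g.
from tumour biopsy or cfDNA studies), optionally requiring the same
methylation trend. Coordinates follow one fixed convention: manifests are
1-based CpG positions, interval files are BED-style 0-based half-open, and
a probe at position $p$ hits $[s,e)$ iff $s \le p-1 < e$. All converters
are centralized, and both overlap engines are verified against an
$O(nm)$ brute-force scan in the test suite.

`geneSetEnrichment()` is transparent plumbing for user-supplied gene sets
(one-sided hypergeometric with BH adjustment). Genes covered by more array
probes are more likely to enter methylation-derived query lists; this
selection bias is *not* corrected here — the `weights` hook only surfaces
per-set mean query weights as a diagnostic.

# Expression integration and the four scenarios

Differential expression (`callDEGs()`) uses a per-gene chi-squared test on
pooled counts: the 2×2 table of (gene counts vs rest-of-library counts) ×
(case vs reference), with expectations proportional to library sizes and no
continuity correction, BH-adjusted at FDR 0.05. The log2 fold change uses
depth-normalized group means with a 0.5 pseudocount. This count test
assumes Poisson sampling; for overdispersed biological replicates the
`method = "welch"` backend (Welch t on log2 normalized counts) is the
appropriate choice.

`classifyScenarios()` joins DEGs with the gene-level methylation summaries
and labels the four canonical promoter/body patterns:

| scenario | expression | methylation pattern |
|---|---|---|
| a | down | ≥1 TSS hyper, 0 body hyper |
| b | up | ≥1 body hyper, 0 TSS hyper |
| c | down | ≥1 body hypo, 0 TSS hypo |
| d | up | ≥1 TSS hypo, 0 body hypo |

"No" opposite-region methylation is read as zero DMPs at the calling
thresholds. Scenarios a/c and b/d may co-occur and are all reported; a/b
and c/d are mutually exclusive through the expression direction. The ≥1
thresholds are configurable (`minTss`, `minBody`) up to the stricter
≥3 TSS / ≥5 body selections used for gene-list refinement.

# The cfDNA biomarker stage

For each patient, cfDNA differentially methylated regions (DMRs) called
between the pre-treatment visit and the on-treatment visit carry a
direction label (hyper/hypo at visit A relative to B). Given a query DMP
signature (typically the hypermethylated tNEPC-state probes),
`overlapDMPsDMRs()` counts DMRs containing at least one query position —
each DMR at most once, tallied by the *DMR's* direction — and
`ratioStatistic()` forms the biomarker
$$r = \frac{n_{hyper} + 0.5}{n_{hypo} + 0.5}.$$
The pseudocount keeps zero-denominator patients defined; a strict mode
excludes them instead. `correlateTTP()` is the Spearman rank correlation
of $r$ with TTP (two-sided p via the t approximation, average ranks for
ties); no censoring model is used, matching the direct-correlation design.

`resamplingNull()` asks whether the observed signature–DMR overlap exceeds
array-placement chance: the observed statistic is the fraction of the $k$
query probes inside any DMR; each of `nIter` (default 10,000) iterations
draws $k$ probes uniformly without replacement from the post-filter
manifest and records its in-DMR fraction, and the one-proportion z-test
$$z = \frac{\hat p - p_0}{\sqrt{p_0(1-p_0)/k}}$$
compares the observed fraction with the resampled mean $p_0$ (two-sided;
sidedness is a reporting choice, made conservative here). The resampling
draws the *same number* of probes as the query — equivalently the query's
percentage of the array — which preserves the only quantity the z-test
needs. Per-patient z-tests are reported without cross-patient adjustment, a
BH column alongside for transparency. DMR-level counting feeds the ratio
(per the biomarker's definition) while DMP-level counting feeds the
resampling proportion; both share one overlap core.

# What the synthetic generator emulates

`simulateManifest()` lays probes on a toy genome of 3 chromosomes × 10 Mb
(coordinates never collide; multi-chromosome coverage exercises the
interval code). Genes occupy non-overlapping slots with TSS windows
(0–1500 bp upstream), UTR/first-exon/body/3'UTR spans; CpG islands cover
most promoters plus random intergenic sites, and context follows from
distance (shore ≤2 kb, shelf ≤4 kb). About 3% of probes carry exclusion
flags. Per-gene probe counts are skewed so that roughly half of genes carry
only 1–2 probes, mirroring how sparsely an array samples most genes.

`simulateBetaSet()` draws baseline betas from a bimodal mixture
(mostly-unmethylated and mostly-methylated modes), plants group-mean shifts
of ±δ (default 0.3, comfortably above the 0.2 call threshold) in a
gene/feature-coherent way — a planted gene has all its TSS probes, or all
its body probes, moved together, so gene-level and scenario stages have
recoverable structure — and adds replicate noise on the logit scale
(default sd 0.12, a beta-scale replicate sd of ≈0.03 at mid-range, typical
of cell-line triplicates; the logit draw keeps every value strictly inside
(0,1), clipped to [1e-6, 1−1e-6]). Planted baselines are kept mid-range so
the ±δ shift is realizable on the beta scale. Default scale: five groups ×
3 replicates with 2000 planted probes per non-reference group, so a planted
|Δβ| = 0.3 effect is recoverable at ≥0.9 sensitivity under the default
thresholds — the design envelope the generator is built to occupy.

`simulateExpression()` draws per-gene counts with lognormal gene means,
lognormal library factors, and Poisson sampling across replicates by
default — deliberately the sampling model the chi-squared count test
assumes, so that null calibration of the DE caller is a meaningful check.
A finite `dispersion` generates negative-binomial overdispersion instead;
on such data the chi-squared test's FDR is *not* controlled, which is
exactly the limitation the Welch backend addresses. Scenario genes (default
4-fold shifts) are chosen among genes whose planted methylation pattern
matches the scenario, one scenario per planted gene.

`simulateCohort()` gives each patient 200–2000 DMRs of 100–2000 bp with a
hyper fraction around one half; a patient-specific signal fraction $f$ of
the hypermethylated DMRs is seeded to contain a planted tNEPC-hyper probe
position. Two TTP constructions are provided. The default (`"signal"`)
draws TTP linearly from the planted burden, `ttp = 500 − 450 f` days plus
Gaussian noise (sd 30): the linear response keeps adjacent patients'
expected TTP spacing comparable across the whole grade, and a cohort with
zero planted signal has TTP exactly independent of the realized overlap
ratio — the correct null for calibration of the correlation step. The
alternative (`"ratio"`) makes TTP a strictly decreasing function of the
realized overlap ratio, which is the construction under which the
noise-free Spearman correlation is −1 identically; it is kept for that
boundary property, but it couples TTP to sampling noise in the overlap
counts and is therefore not the calibration default. TTP is in days with
no censoring.

What the generator does **not** emulate: array chemistry (type I/II probe
bias, dye effects — hence the identity normalization default), IDAT-level
data, read-level bisulfite counts, batch structure, correlated probe blocks
beyond the planted gene-feature coherence, biological overdispersion of
expression by default, and censored survival outcomes. Passing recovery
tests therefore certify the statistical machinery under the stated models,
not robustness to those real-data complications.

# Numerical and design choices

* **Ties and determinism.** Heatmap ranking breaks min-q ties by larger
  |Δβ|, then probe id; every generator stage is a pure function of its
  seed; pipeline runs are byte-reproducible given the config.
* **Degenerate inputs.** Zero-variance probes with zero delta are reported
  non-significant, never NaN; empty DMR sets flag rather than fail;
  zero-denominator ratio patients are regularized (or excluded in strict
  mode); resampled null proportions of exactly 0 or 1 short-circuit the z
  statistic; empty filter results warn rather than error.
* **"More than 5 DMPs"** is read literally as ≥6, with the inclusive ≥5
  exposed, since published gene tallies can reflect either reading.
* **Problem sizes.** The test suite and acceptance script run the caller
  calibration at 50,000 probes (2 groups × 3 replicates), the staged study
  at 20,000 probes/1500 genes, cohort recovery over replicate 20-patient
  cohorts, and the resampling calibration at 1000 iterations per run —
  desk-scale versions of the full design chosen to keep the whole suite
  reproducible in minutes on one CPU.
* **Sidedness.** Resampling z-test p values are two-sided (conservative;
  the enrichment direction is of interest but depletion is not asserted).

# Known limitations

* The chi-squared DE test is anti-conservative on overdispersed counts;
  use the Welch backend for biological replicates (see above).
* The hypergeometric enrichment ignores probe-count selection bias; treat
  its p values as descriptive unless the query derivation is
  coverage-balanced.
* Whether the original staged studies tested beta or M values, and whether
  their gene partitions used the count comparison or a ratio statistic, is
  not always published; `net_class` (count comparison) is used for
  partition-type claims and the log-ratio score for ranking.
* Spearman-with-TTP has no censoring model; cohorts with early dropouts
  need a survival treatment outside this package's scope.
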