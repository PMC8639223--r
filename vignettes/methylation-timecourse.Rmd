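---
title: "Tracking DNA-methylation remodeling during T-cell product expansion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking DNA-methylation remodeling during T-cell product expansion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methexpand)
```

## The problem

Regulatory T cells (Tregs) manufactured for adoptive cell therapy are
expanded *in vitro* for weeks under repeated TCR stimulation. That
expansion leaves marks on the DNA methylome: promoters of activation genes
demethylate, partially methylated domains (PMDs) lose methylation with
every accumulated cell division, and — most worryingly — the Treg-specific
demethylated regions (Treg-DRs) that define Treg identity (FOXP3's TSDR
enhancer, loci in *IKZF2*, *IL2RA*, *TNFRSF1B*, ...) begin to
*re*methylate, signalling a possible destabilization of the suppressive
phenotype. **methexpand** packages the analysis chain needed to quantify
these effects from Infinium-style beta-value matrices: probe QC,
normalization, batch adjustment, moderated-t differential methylation,
kernel-smoothed DMR calling, cross-run kinetic classification, and the
PMD / Treg-DR / exhaustion signature analyses — together with a
synthetic-data generator that plants all of those effects with known
truth, so every stage is testable without any external download.

## The model, stage by stage

### Values and scales

A CpG's methylation is a **beta value** in $[0,1]$. Statistics are
computed on **M values**, $M = \log_2\frac{\beta + a}{1 - \beta + a}$ with
a symmetric offset $a = 10^{-3}$ (configurable) keeping $M$ finite at the
boundaries. M values have approximately constant variance across the beta
range, which is what the linear models below assume; effect sizes are
reported back on the beta scale (`delta_beta`), where they are
interpretable as methylation-fraction changes.

### Probe QC

`filterProbes()` removes probes that fail the detection p-value threshold
($p \ge 0.05$) in *any* sample, are cross-reactive, were dropped by the
vendor, or interrogate a CpG within 3 nt of a SNP. The "any sample" rule
is the conservative choice for small sample sizes; the per-reason removal
report is kept on the object. `dropSexChromosomes()` removes chrX/chrY
probes before differential analysis (sex is a nuisance covariate here).

### Quantile normalization — and its known limitation

`quantileNormalize()` forces all samples onto the mean of their sorted
value vectors (ties by average rank). This removes technical
distribution-level differences, but it *assumes there is no genuine
global shift*. A real global shift — such as PMD hypomethylation
accumulating with expansion — is partially redistributed by QN onto
unaffected probes as small (~0.01–0.03 beta) spurious opposite-direction
shifts concentrated in the mid-beta range. The pipeline applies QN in the
canonical order (QN, then M conversion, then batch adjustment) because
that is the standard chain for this assay; users tracking strong global
drift should be aware that per-probe contrasts computed after beta-matrix
QN carry this artifact, and the package's own statistical validation of
the differential stage is therefore performed on filtered, un-normalized
M values.

### Batch adjustment

`combatAdjust()` implements the parametric empirical-Bayes location/scale
model: per-probe standardization given the protected covariates, per-batch
additive ($\gamma$) and multiplicative ($\delta^2$) effects shrunk toward
moment-matched batch-level priors (normal for $\gamma$, inverse-gamma for
$\delta^2$), iterated to convergence, then removed. With a single batch it
is the identity; singleton batches and batch/covariate confounding are
errors. The non-parametric variant is intentionally out of scope. On data
with a planted additive shift the adjustment removes $\ge 98\%$ of the
between-batch variance while perturbing planted day effects by under 1%
(see `test-acceptance.R`).

### Per-CpG differential methylation (DMPs)

`fitDmps()` fits, per probe, an ordinary linear model of M on the contrast
group plus an optional donor blocking factor (the default in within-run
contrasts, since the same three donors appear at every time point).
Residual variances are shrunk by empirical Bayes,

$$ s^2_{\text{post}} = \frac{d_0 s_0^2 + d\, s^2}{d_0 + d}, $$

with the prior $(d_0, s_0^2)$ estimated by moment matching on log
variances (the trigamma-inversion estimator; $d_0$ capped at $10^6$ for
numerical stability). The moderated $t$ has $d_0 + d$ degrees of freedom;
p-values are two-sided and BH-adjusted (significant means FDR < 0.05).
Probes that are constant across samples get $p = 1$ by convention. The
implementation is checked in the test suite against an independent
reference EB implementation (limma) to $10^{-10}$.

### Kernel-smoothed DMR calling

`smoothStats()` aggregates evidence along the genome: squared per-CpG
statistics are smoothed with a Gaussian kernel of bandwidth
$\sigma = \lambda / C$ ($\lambda = 500$ bp, $C = 3$), truncated at
$\pm\lambda$:

$$ Y_i = \frac{\sum_j w_{ij} z_j^2}{\sum_j w_{ij}}, \qquad
   w_{ij} = e^{-(x_i - x_j)^2 / 2\sigma^2}. $$

Two numerical choices matter here and were made deliberately:

1. **Probit calibration.** Moderated $t$ with $\nu$ df has
   $E[t^2] = \nu/(\nu - 2) > 1$, so squaring raw $t$ inflates $Y$ under
   the null. Statistics are first mapped to the normal scale,
   $z = \Phi^{-1}(P_t(t; \nu))$, which is exactly $N(0,1)$ under the null.
2. **Four-moment null.** Under working independence $Y_i$ is a weighted
   sum of $\chi^2_1$ variables. The classical two-moment (Satterthwaite)
   scaled-chi-square fit is measurably anticonservative in the far tail
   (~2x at $p \sim 10^{-4}$ in our calibration runs), which across $10^4$
   CpGs produces frequent false regions. The package instead matches four
   moments to a noncentral chi-square (the Liu–Tang–Zhang approximation),
   which is exact for an isolated CpG ($Y = z^2 \sim \chi^2_1$) and
   calibrated at the tail probabilities BH actually uses.

`callDmrs()` then BH-adjusts the smoothed p-values, groups significant
CpGs whose consecutive gaps are $\le \lambda$, discards regions with fewer
than 3 CpGs, splits mixed-direction regions at sign changes of the
per-CpG `delta_beta` runs (a DMR is hyper or hypo, never "net"), and
scores each region by Stouffer combination of its member per-CpG DMP
p-values — *not* the smoothed p-values, which are dependent by
construction:

$$ Z = \frac{1}{\sqrt{n}} \sum_i \Phi^{-1}(1 - p_i / 2)\, s_i, $$

with $s_i = \pm 1$ the CpG's direction relative to the region. Regions
with one-sided combined $p \ge 0.05$ are dropped. Region intervals are
0-based half-open; BED6 export encodes direction in the name and
$-\log_{10} p$ in the score.

### Shared DMRs and Early/Late kinetics

`matchSharedDmrs()` declares a run-1 DMR *shared* when run-2 DMRs of the
same direction cover at least 50% of its length (the denominator is the
run-1 DMR, matching the one-directional phrasing of the rule; a symmetric
mode is available by flag). The matched partner is the largest single
contributor; a run-1 DMR whose best-overlapping run-2 DMR has the
opposite direction is counted as discordant and excluded.

`classifyKinetics()` operationalizes "first identified": a DMR is
**early** when present (same 50% + direction rule) in both the
day-10-vs-day-0 and day-23-vs-day-0 DMR sets of its run, **late** when
present only at day 23, and **none** otherwise — including the
day-10-only case, a transient change that did not persist. The paper-level
notion of cross-contrast identity is not defined anywhere authoritative;
the 50%-overlap operationalization is this package's stated convention.

### Signatures

* `pmdMedianTrack()` — per-sample median beta over the PMD core set
  (`intersectRegionSets()` builds core sets from multiple subset PMD
  BEDs), joined with the cumulative expansion rate. PMD methylation loss
  is proportional to accumulated divisions, hence modeled and tested
  against $\log_{10}$ expansion.
* `stabilityRegression()` / `stabilityScreen()` — per CpG, OLS of beta on
  $\log_{10}$(cumulative expansion rate). A CpG is **destabilized** when
  $R^2 > 0.4$ *and* $p < 0.05$. We regress beta on expansion (not the
  reverse): $R^2$ and the classification are unaffected by exchanging
  axes, and this orientation yields a slope in beta per
  $\log_{10}$-expansion unit. At $n = 9$ the two classification
  conditions nearly coincide ($p < 0.05 \iff R^2 > 0.44$), so for a truly
  stable locus the per-CpG false-destabilization rate is the test level
  (~5%). Locus-level calls therefore use the majority of member CpGs,
  which drops the locus-level false rate below 1%; both levels are
  reported.
* `wgbsDmps()` / `wgbsDmrs()` — bisulfite count tables are joined by
  coordinate, filtered to $\ge 10\times$ coverage in both groups, tested
  with a pooled two-proportion z (an approximation chosen over
  dispersion modeling, which is out of scope), BH-adjusted, and fed
  through the same smoothing/grouping/Stouffer machinery as the array
  DMRs.
* `exhConcordance()` — overlap (>= 50% of the shared DMR) of Late shared
  DMRs with exhaustion DMRs, with per-direction concordance and the
  promoter fraction among concordant-hypermethylated regions.

### Enrichment

`oraHypergeometric()` is the upper-tail hypergeometric test with BH across
terms; the pipeline's universe is the set of genes annotatable from probes
surviving preprocessing (array-coverage bias control), not the whole
genome. `gseaPreranked()` implements the weighted KS running-sum ES with a
gene-label permutation null, $NES = ES / \overline{|ES^0_{\text{same
sign}}|}$, and a $+1$-corrected empirical p (so $p \ge 1/(N_{perm}+1)$);
its ES agrees with the reference implementation (fgsea) to $10^{-10}$ in
the test suite.

## What the synthetic data emulate

`simDesign()` + `simulateManifest()` + `simulateTimecourse()` generate an
EPIC-like experiment: 10,000 probes in CpG-island-like clusters on 4
autosomes (plus a small chrX/chrY contingent), 3 donors x 2 manufacturing
runs x days (0, 10, 23), with:

* baseline beta from a bimodal mixture (low mode ~0.1, high ~0.85, a 15%
  intermediate shoulder, as real array distributions show);
* 20 planted DMRs of 5 CpGs, $\Delta\beta = 0.2$, 60% hyper, half with
  early-saturating kinetics ($\ge 80\%$ of the effect by day 10) and half
  late-onset (no effect through the intermediate day, quadratic rise to
  the final day — a Late region is by definition not yet changed when
  first assayed);
* PMDs covering 20% of the genome, drawn preferring probe-poor segments
  (PMDs are gene-poor and arrays under-sample them), whose probes lose
  0.05 beta per $\log_{10}$ expansion unit;
* Treg-DR loci whose probes start near 0.07 and gain 0.15 beta per
  $\log_{10}$ expansion unit — except the FOXP3-like and TNFRSF1B-like
  anchor loci, which stay flat (the stable-demethylation behavior of the
  TSDR);
* donor random intercepts, per-run additive + multiplicative batch
  effects, and Gaussian noise — all on the M scale, the scale on which the
  batch-correction and differential models operate; per-probe
  heteroscedasticity is deliberately *not* modeled, because the EB
  moderation assumes exchangeable variances (a nonzero `tregdrNoiseSd`
  stress knob exists for exploring violations);
* a detection-p matrix with a 0.2% failure rate, and cumulative expansion
  rates growing to ~$10^3$-fold by day 23 with donor/run jitter.

`simulateWgbs()` generates per-CpG methylated/total counts for two groups
at ~100 bp CpG spacing with negative-binomial coverage (overdispersed) and
binomial methylated counts; planted blocks shift group A by a fixed delta,
with baselines clamped to leave room for the full effect.

What the generator does **not** emulate — and hence what green tests do
not certify about real data: probe-type chemistry differences (Infinium
I/II), spatial chip artifacts, cell-composition shifts, SNP-driven
trimodality, correlated (co-methylated) noise beyond the planted
structure, and per-probe variance heterogeneity. Results on real arrays
additionally depend on upstream IDAT preprocessing, which is out of scope
(the pipeline starts at beta + detection-p matrices).

## Parameters that matter

| Parameter | Default | Where | Meaning |
|---|---|---|---|
| detection-p threshold | 0.05 | `filterProbes` | keep probes with p < 0.05 in all samples |
| SNP window | 3 nt | `filterProbes` | drop CpGs within 3 nt of a variant |
| M offset | 1e-3 | `betaToM` | boundary clipping |
| FDR threshold | 0.05 | `fitDmps`, `callDmrs` | BH significance |
| lambda | 500 bp | `smoothStats`, `callDmrs` | kernel truncation and grouping gap |
| C | 3 | `smoothStats` | bandwidth divisor, sigma = lambda / C |
| min CpGs | 3 | `callDmrs` | smallest reportable region |
| Stouffer threshold | 0.05 | `callDmrs` | region-level combined p |
| shared overlap | 0.5 | `matchSharedDmrs`, `classifyKinetics` | coverage rule |
| WGBS coverage | 10x | `wgbsDmps` | per-group floor |
| R-squared | 0.4 | `stabilityRegression` | destabilization call (with p < 0.05) |
| promoter window | ±3000 bp | `annotatePosition` | around the strand-aware TSS |
| downstream window | 300 bp | `annotatePosition` | past the gene 3' end |

The promoter and downstream windows and the midpoint rule for region
annotation are annotation-tool conventions, configurable and flagged in
output metadata; the priority order is fixed
(promoter > 5'UTR > 3'UTR > exon > intron > downstream >
distal intergenic, ties by distance to the nearest TSS).

## Numerical and degenerate-input choices

* Chromosome labels are normalized ("1" = "chr1") at load time; BED is
  0-based half-open on disk, GFF3 1-based inclusive, both converted to the
  internal 0-based half-open convention (array manifests' 1-based `pos`
  column is converted at the probe-lookup boundary).
* p-values are clamped at $10^{-300}$ before probit transforms.
* Stouffer input p of exactly 1 contributes $z = 0$ with its sign.
* `stabilityRegression` on perfectly linear or constant input returns
  $R^2$ of exactly 1 or 0 without warnings; constant expansion is an
  error.
* ComBat's EB iteration converges at $10^{-4}$ relative change, capped at
  200 iterations; covariate columns that are constant (an intercept) are
  dropped because the batch dummies span them.
* PCA components are signed so the largest-magnitude loading is positive.
* `evaluateDmrCalls` masks PMD/Treg-DR intervals from precision: calls
  there detect real planted non-DMR signal.

## Simulation scales used by the checks

The statistical acceptance checks in `tests/testthat/test-acceptance.R`
use: 25 seeds of the full default design for DMR recovery and for
kinetics; 100 null seeds at 2,000 probes for FDR control; 1,000 random
instances for the smoothing oracle; 50 seeds at 100 probes x 12 samples
for batch recovery; 200 seeds at $n = 9$ for the stability regression
(slope 0.1, noise 0.02 for CI coverage; slope 0.15 vs 0, noise 0.03 for
the locus classes); 500 random instances for the interval oracles; and a
2,500-probe design for byte-level pipeline determinism. These sizes are
the package's chosen validation conditions; `scripts/acceptance.R`
recomputes the same quantities at comparable sizes from a single seed.

## Known limitations

* Beta-matrix quantile normalization redistributes genuine global shifts
  (see above); consider skipping QN when strong PMD drift is the signal
  of interest.
* The WGBS test is a pooled two-proportion z on collapsed replicates; it
  ignores biological dispersion between replicates and will be
  anticonservative when that dispersion is real.
* The working-independence assumption in the smoothed-statistic null
  ignores co-methylation; the four-moment tail fit calibrates the marginal
  null, not the joint one.
* GSEA uses gene-label permutation; it preserves the ranking's
  correlation structure but not gene-gene correlation within sets.
* `run_pipeline`'s enrichment stage builds a toy gene-set collection in
  synthetic mode; supply a GMT for real analyses.

## A short tour

```{r tour, eval = FALSE}
design <- simDesign(seed = 1)
bundle <- simulateManifest(design)
tc <- simulateTimecourse(design, bundle)

me <- filterProbes(tc$me, bundle$manifest)
me <- dropSexChromosomes(me, bundle$manifest)
meM <- convertToM(me)

sheet <- sampleSheet(me)
ctr <- makeContrast("day23_vs_day0_R1",
                    sheet$sample_id[sheet$run == "R1" & sheet$day == 23],
                    sheet$sample_id[sheet$run == "R1" & sheet$day == 0],
                    block = setNames(sheet$donor, sheet$sample_id))
dmps <- fitDmps(meM, ctr, bundle$manifest, meBeta = me)
dmrs <- callDmrs(smoothStats(dmps))
evaluateDmrCalls(dmrs, tc$truth)

# or the whole chain at once:
run <- runPipeline(pipelineConfig("out", seed = 1))
```
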