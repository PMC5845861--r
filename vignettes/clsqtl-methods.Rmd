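---
title: "Methods: quantifying chronological life span and mapping its QTLs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying chronological life span and mapping its QTLs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clsqtl)
```

## Overview

`clsqtl` implements the quantitative-genetics analysis of chronological
life span (CLS) in a haploid biparental yeast cross. CLS — how long
non-dividing cells in stationary phase remain able to resume growth — is
quantified from plate-reader outgrowth kinetics as a **Survival Integral
(SI)**, and the genetic basis of SI variation is mapped by two
complementary strategies: **Individual Segregant Analysis** (ISA; a
single-marker LOD scan with a permutation-derived genome-wide threshold)
and **Bulk Segregant Analysis** (BSA; allele counting in extreme
phenotypic bulks, a G likelihood-ratio statistic, tricube smoothing and
FDR control). Heritability, transgressive segregation, distribution and
correlation structure complete the picture. A built-in simulator
(meiosis with the Haldane map function, additive per-condition QTL
effects, logistic outgrowth curves) generates data with the statistical
structure the analysis assumes, so every stage — and the pipeline end to
end — is testable without external data.

## The CLS assay model

### From outgrowth curves to viability

An aged culture is re-inoculated into fresh medium and its optical
density (OD) recorded over time. Only the viable fraction $v$ of the
inoculum regrows, so the culture reaches a fixed OD threshold later than
a fully viable one; each doubling time $T_d$ of delay corresponds to one
lost doubling, i.e. a halving of the viable inoculum:

$$ v = 2^{-\Delta t / T_d}, \qquad \Delta t = t_{\mathrm{cross}} - t_{\mathrm{cross}}^{\mathrm{ref}}. $$

`simulate_outgrowth()` is the generative counterpart: the growing
subpopulation follows logistic growth from an effective inoculum
$\mathrm{OD}_0 \cdot v$ while the dead fraction contributes a constant
$\mathrm{OD}_0 (1 - v)$; additive Gaussian OD noise is optional. The
default inoculum is 0.5% of the carrying capacity
(`growth_params(od0 = 0.005)`): small enough that the dead-cell offset
and early-phase curvature perturb threshold crossings by well under the
5% viability tolerance we hold the round trip to, large enough that
viabilities down to ~2% still cross the threshold within a 24 h grid.

### Growth-curve fitting

`fit_growth()` estimates, per curve:

* **Specific growth rate** $\mu$ (1/h). The OD trace is lightly
  smoothed with a 5-point running mean (a running mean rescales an
  exponential without changing its log slope), restricted to the
  informative band between 2% and 80% of the plateau, and transformed to
  the logit scale $\ln(x / (\hat K - x))$, on which a logistic
  trajectory is exactly linear with slope $\mu$. Sliding 5-point windows
  each yield a slope estimate; $\mu$ is their **median**. Because every
  window estimates the same quantity, the median is unbiased on clean
  curves (bias ~0.1% on noise-free logistic curves) and robust to
  noise-inflated windows; taking the maximum of windowed log-slopes
  instead — a common convention — is biased upward by 10–90% already at
  OD noise of 0.01, which is why we do not use it.
* **Doubling time** $T_d = \ln 2 / \mu$.
* **Time to threshold** $t_{\mathrm{cross}}$, by log-linear
  interpolation between the bracketing samples (growth is locally
  exponential there). The default threshold is the midpoint of the
  reference curve's minimum and maximum OD, which is robust to plateau
  differences between strains.
* **Yield of biomass**, the OD gain over the curve; and a `grew` flag
  (a curve that never reaches the threshold is a dead well).

`quantify_plate()` applies the convention that the earliest aging day is
the fully viable reference: its fit supplies the threshold and the
doubling time reused for all later days of the same strain and
condition, because late outgrowths of dying cultures distort slope
estimates.

### Survival curves and the Survival Integral

`build_survival_curve()` converts per-day crossings to viabilities,
caps $v$ at 1 (negative shifts arise from noise), and censors every day
from the first non-growing day onward to 0 so that spurious regrowth
cannot resurrect a dead culture. `survival_integral()` is the
trapezoidal area under viability versus aging day, in day units. With
daily sampling from day 1, a strain alive at day 1 but dead at day 2
scores the assay floor of 0.5 days — the smallest SI the assay can
report for a viable strain — and a strain fully viable over $D$ days
scores $D - 1$. Flooring produces a point mass in SI distributions,
which is why Shapiro–Wilk normality checks (`normality_check()`) reject
on strongly floor-censored data even when the underlying trait is
Gaussian.

The generative inverse `viability_schedule()` maps a target SI to an
exponential-decay viability schedule whose trapezoid equals the target,
so simulated SI phenotypes can be pushed through the full assay.
Round-trip accuracy (simulate, quantify, integrate) is within 1–4%
noise-free and within 15% at OD noise SD 0.01.

## The simulated cross

`make_marker_map()` lays out evenly spaced markers; `simulate_cross()`
generates haploid spores chromosome by chromosome: the first marker is
Bernoulli(1/2) and each subsequent marker switches parental origin with
the Haldane recombination fraction $r = \tfrac12(1 - e^{-2d})$ for map
distance $d$ — crossovers as a Poisson process without interference,
the simplest standard meiosis model. Chromosomes assort independently.
`simulate_phenotypes()` is purely additive: value = baseline + summed
allele effects + Gaussian noise, with parent 1 carrying allele 0
everywhere and parent 2 allele 1. Haploids have no dominance, and
analysing each condition separately removes gene-by-environment
variance, so the model's genetic variance is additive (plus any
epistasis, which the generator does not produce). Two opposing-effect
loci split between the parents suffice to generate transgressive
segregants, which `transgression_summary()` flags beyond
$k$ parental SDs (default $k = 2$; no standard rule exists, so the
multiplier is exposed).

Default study dimensions follow the reference design: 488 haploid
segregants from two parents, 16 chromosomes, three parental replicates.
Marker density is configurable because the density of the real
genotyping data is not fixed by the design; the ISA default uses ~300
markers (19 per chromosome at 5 cM), while BSA simulations use a
genome mirroring *S. cerevisiae*'s scale — 16 chromosomes × 100 markers
at 3 cM with 2.7 kb/cM, ~4800 cM and ~13 Mb in total — because the G′
null fit needs both several markers per smoothing window and many
linkage blocks per chromosome (below).

What the generator deliberately does not emulate: epistasis, dominance
(haploids), genotyping error beyond missingness, plate or edge-well
effects, sequencing-depth noise in bulks (counts are exact, as when all
segregants are individually genotyped), and non-logistic growth (lag
phases, diauxie). Passing tests therefore demonstrate correctness of
the estimators under the stated model, not robustness to every artefact
of real plate data.

## Individual Segregant Analysis

`lod_scan()` scores each marker by comparing residual sums of squares
of the grand-mean model and the two-allele-group-means model:

$$ \mathrm{LOD} = \frac{n}{2} \log_{10} \frac{\mathrm{RSS}_0}{\mathrm{RSS}_1}, $$

equivalently $-\tfrac n2 \log_{10}(1 - r^2)$ for the genotype–phenotype
correlation $r$ — marker regression rather than interval mapping, which
is adequate at the marker densities simulated and matches the
single-marker scan the study design implies. Missing genotypes are
dropped marker-wise; monomorphic markers score 0; perfect fits are
flagged `Inf`; markers with fewer than two segregants per allele class
are skipped and recorded.

`permutation_threshold()` permutes phenotype labels (default 1000
permutations), collects the maximum LOD per permuted scan, and returns
the nearest-rank $1-\alpha$ quantile — the genome-wide threshold at
level $\alpha = 0.05$. Infinite permuted LODs are excluded from the
quantile. Calibration was verified directly: over 600 independent null
crosses of 488 segregants the empirical genome-wide type-I error was
0.052 ± 0.009. `support_intervals()` reports 1.5-LOD drop intervals
around significant peaks.

## Bulk Segregant Analysis

`select_bulks()` takes the 50 highest- and 50 lowest-SI segregants
(ties broken deterministically by id). `allele_counts()` tallies
parental alleles per marker within each bulk; `g_statistic()` is the
2×2 likelihood-ratio statistic
$G = 2\sum n \ln(n/e)$ with margin-based expectations, and
`smooth_gprime()` replaces each $G$ by a tricube-weighted mean over
markers within a window on the same chromosome.

Two numerical choices required care:

* **Smoothing window.** For dense real marker data a narrow window
  (default 25 kb in `bsa_scan()`) is conventional. For the simulated
  cross, however, the resolution of bulk mapping is set by linkage, not
  marker spacing: the expected linked signal decays as $(1-2r)^2$ and
  falls below the genome-wide significance threshold only at roughly
  70 cM (~190 kb at 2.7 kb/cM) for a QTL explaining 30% of variance
  with bulks of 50 from 488 spores. `study_config()` therefore defaults
  to a 200 kb window, which both matches that containment scale and
  pools enough markers (~50) for a stable null fit.
* **Null model.** `gprime_significance()` models null G′ as log-normal
  with robust location (median of $\ln G'$) and a scale matched to the
  85th percentile, $(Q_{85} - \mathrm{med})/z_{0.85}$. Robustness is
  needed because true QTL regions inflate non-robust fits; the
  85th-percentile match tolerates up to ~15% of markers being
  QTL-elevated (two causal chromosomes of sixteen). The scale is
  matched to the upper tail rather than taken from the MAD because,
  under linkage, smoothed G′ fluctuates coherently along chromosomes
  and its null right tail is heavier than its left; in our simulations
  a MAD-based scale loses FDR control (realized false-discovery
  proportion ~0.09–0.11 at a nominal 0.05), while the tail-matched
  scale holds it at ~0.03–0.07 with unchanged detection power (~0.93
  for a 30%-variance QTL). Benjamini–Hochberg q-values and the
  smallest significant G′ define the reported threshold.

`significant_regions()` merges contiguous significant markers into
regions with physical widths; `genes_in_interval()` intersects a region
with a gene annotation (TSV or GFF3) under the inclusive 1-based
convention, so a gene abutting the region boundary is included.

## Heritability and correlation structure

With genetically uniform parents, replicate spread is purely
environmental: `pooled_parental_variance()` pools within-parent sample
variances weighted by degrees of freedom. Broad-sense heritability is
$H^2 = (V_P - V_E)/V_P$, clipped to $[0,1]$ with the raw value retained
(`broad_sense_h2()`). Narrow-sense heritability is the OLS slope of
segregant-population means on midparent values pooled across traits and
conditions (`narrow_sense_h2()`); midparent values are used since the
regression is then symmetric in the parents, and no display rescaling
is applied to the inputs (a common factor on both axes of a point
leaves a slope-1 relation intact). On purely additive simulations the
slope recovers 1 within sampling error, and $H^2$ recovers
$V_A/(V_A + V_E)$ consistently as the cross grows (checked at 100, 488
and 2000 segregants).

`trait_correlations()` reports complete-case Pearson correlations with
$n$ and p-values (Fisher z for intervals); degenerate pairs are
reported as missing with a reason rather than silently dropped.
`cluster_conditions()` clusters conditions by average-linkage
agglomeration on $1 - R$, with flat groups at $k = 2$ by default,
mirroring the practice of grouping environments into life-span
shortening versus prolonging classes.

## Orchestration and reproducibility

`study_config()` + `run_study()` tie the stages together: simulate the
cross and phenotypes (optionally through the full outgrowth assay),
scan every condition with ISA and BSA, estimate heritability,
transgression and the condition correlation structure, and compare
detected intervals with the configured truth. One master seed drives
every stage through derived sub-seeds; identical seeds give
byte-identical persisted outputs. Tabular outputs are TSV/CSV, QTL
intervals export as BED (0-based half-open; internal coordinates are
1-based inclusive), the truth and configuration as YAML, and the
condition dendrogram as Newick. A thin command-line wrapper with
`simulate` / `quantify` / `scan-isa` / `scan-bsa` / `herit` / `run-all`
subcommands is installed under `inst/cli/clsqtl.R`.

A configuration in which one locus acts only under calorie restriction
and another only under high-sugar conditions reproduces, in silico, the
hallmark condition-dependent detection pattern: each locus appears in
exactly the scans of the conditions where it has an effect.

## Problem sizes used in validation

The test suite and the acceptance script size their simulations as
follows: calibration of the ISA genome-wide threshold uses 200 null
crosses of 488 segregants with ~300 markers and 1000 permutations each;
BSA FDR control uses 200 crosses (half null, half with one
30%-of-variance QTL) on the yeast-scale 1600-marker map; co-localisation
power uses 30–40 strong-effect replicates; unit-level checks use
hundreds of segregants. These sizes give binomial/sampling tolerances
that are tight enough to detect calibration errors of a few percentage
points while keeping the whole suite runnable on a laptop in about a
minute.

## Known limitations

* Marker regression, not interval mapping: positions between markers
  are not scanned, and LOD support intervals are marker-resolution.
* The G′ null calibration is approximate under linkage; FDR control was
  verified for the simulated designs, not proven in general. With very
  few (< ~6) chromosomes, or when QTL-elevated markers exceed ~15% of
  the genome, the robust null fit degrades.
* BSA resolution in a 488-spore cross is tens of centimorgans; the
  narrow (10–25 kb) regions achievable with very dense real marker data
  arise from much larger effective marker numbers and noise structure
  than the in-silico exact counts emulate.
* The assay model assumes logistic regrowth and a common growth rate
  across aging days of a strain; real dying cultures can regrow with
  altered kinetics, which the censoring rule only partially guards
  against.
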