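---
title: "Detecting variegated loss of heterozygosity in allele-specific expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting variegated loss of heterozygosity in allele-specific expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vloh)
library(dplyr)
```

## The problem

In an F1 hybrid, every informative germline SNV distinguishes the two
parental strains, so RNA-seq reads can be assigned to a parental allele at
each expressed SNV (eSNV). In a balanced cell both alleles contribute about
equally; an allelic ratio far from 1:1 marks loss of heterozygosity (LOH)
at the expression level. `vloh` analyses a cohort of F1 tumor samples
(strain A, FVB-like; strain B, BALB-like) and separates three phenomena:

1. **Clonality**: X-inactivation is mitotically heritable, so a tumor
   descended from one cell expresses chrX almost exclusively from one
   parent. Per-tumor mean chrX CAF (the strain-B allele frequency,
   `count_b / (count_a + count_b)`) below 0.25 or above 0.75 is read as a
   clonal call.
2. **Concerted LOH**: chromosome- or segment-scale skew shared by the whole
   cohort (monosomy, a hemizygous deletion). These regions are genetic, not
   stochastic, and are masked before outlier analysis.
3. **Variegated LOH (V-LOH)**: sparse, tumor-private allelic-ratio
   outliers. At each unmasked eSNV the cohort defines a distribution;
   sample $i$ is standardized as
   $Z_i = (x_i - \mu) / \sigma$
   with $\mu$ and $\sigma$ the mean and sample standard deviation across
   the cohort *including* sample $i$, and flagged as an outlier when
   $|Z_i| \ge 2$ (signed: a positive flag means excess strain-B signal).

Two cohort-level statistics follow. Gene-level outlier **enrichment**: with
$n$ samples and a nominal per-sample outlier rate $r$ (default the
$1/20$ convention), the chance a gene shows no outlier in any tumor is the
Poisson zero class $e^{-nr}$ (0.3679 at $n = 20$, $r = 1/20$); the observed
number of zero-outlier genes is compared by a one-sided exact binomial
test. A **correlation screen**: each tumor's eSNV outlier burden is
correlated (Pearson, two-sided t p-values) with every gene's expression
across the tumors free of private concerted LOH; hits pass
$|r| > 0.7$ and $p < 0.01$, hit-rate enrichment is a one-sided binomial
tail against an assumed 1% chance rate, and the fraction of negative signs
among very strong correlations ($p < 10^{-6}$) summarizes the direction of
the coupling.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `min_minor` | 15 reads | minimum minor-strain (or total) read support per site |
| `skew_low`, `skew_high` | 0.25 / 0.75 | strict skew thresholds on mean CAF |
| `loh_alpha` | $10^{-3}$ | level of the region location test |
| `min_run` | 10 sites | minimum run of skewed sites for a segment |
| `z_thresh` | 2 | outlier threshold on the cohort Z-score |
| `per_sample_rate` | 1/20 | nominal per-tumor outlier rate of the Poisson null |
| `min_level` | 0.5 log2 RPKM | expression floor for the correlation screen |
| `r_cut`, `p_cut` | 0.7 / 0.01 | dual hit threshold of the screen |
| `null_rate` | 0.01 | assumed chance rate of a hit-magnitude correlation |

Where the wording of the source conventions is ambiguous, both readings are
implemented and the choice is explicit:

* **Filter scope.** The read-support rule can be applied to the
  cohort-summed minor-strain count (default), per sample (stricter), or to
  total depth (`rule = "total"`). Under the minor-allele rule a fully
  hemizygous region removes itself from the data — its minor-strain count
  is zero — so the deletion is excluded either way: dropped by the filter,
  or masked by the scan when the total-depth rule is used.
* **SD convention.** Sample SD ($n - 1$) everywhere, with a population-SD
  flag. At $n = 20$ the difference is ~2.6% of the SD.
* **Z boundary.** $|Z| \ge 2$ inclusive by default; a strict
  `boundary = "exclusive"` is selectable. At continuous CAF values the two
  differ on a measure-zero set.
* **Region test.** The location test behind a concerted-LOH verdict is a
  two-sided one-sample t-test of per-site mean CAF against 0.5, with an
  exact sign test when the site means are degenerate (a deletion gives all
  zeros) or fewer than five. This is a convention: the upstream analyses
  report skew p-values without naming a test.
* **Retained tumors.** For burden counting a tumor is excluded when any
  unmasked autosome shows a private chromosome-scale skew (mean CAF beyond
  the thresholds over at least 10 unmasked sites). Cohort-wide events are
  already masked, so this drops only privately aberrant tumors.

## What the simulator emulates

`sim_config()` / `simulate_ase()` generate the cohort the analysis assumes:
20 tumors; 600 eSNVs on each of 19 autosomes plus 300 on chrX (3
consecutive sites per gene); per-site baseline CAF drawn from a Gaussian
with mean 0.511 and SD 0.096, clipped to $[0.05, 0.95]$ to avoid degenerate
sites; clonal X-inactivation per tumor (effective chrX CAF 0.05 or 0.95 —
strong, not absolute, skew); one whole-autosome loss shared by all tumors
(chr4, residual CAF 0.15); a fully hemizygous segment at the start of chr7
(CAF exactly 0); sparse planted gene-level events (probability 0.05 per
gene and tumor, CAF shift ±0.3 on all the gene's sites); and a 5% subset of
genes whose expression is coupled to the tumor's planted-event burden with
slope −3 expression units per event and Gaussian noise (SD 1).

Read depth per site and sample is negative-binomial (mean 100, size 5) and
the strain-B count is beta-binomial with intra-class correlation 0.01
(binomial at 0). The depth distribution and the overdispersion level are
conventions — the source data do not state them — chosen as typical of
gene-collapsed RNA-seq allele counts; the baseline CAF spread (0.096) is
carried by the across-site distribution, not by sampling noise.

Two deliberate departures from a literal reading of the generative recipe:

* **Planting location.** Stochastic events are planted only on chromosomes
  free of clonal aberrations. An event inside a concerted-LOH region is
  masked before outlier analysis, so planting it there would make
  ground-truth sensitivity undefined rather than measurable.
* **Centered repression coupling.** Expression of a coupled gene is
  `baseline + slope × (planted burden − mean burden) + noise`. Centering
  the burden keeps coupled genes at a realistic mean level (so they survive
  the 0.5 log2 RPKM floor) and leaves every correlation untouched.

The simulator does *not* model reference-mapping bias, imprinting,
multi-clone mixtures, batch effects, or gene-length/GC effects on
expression. Passing recovery tests therefore shows the statistical
machinery is correct under the stated model, not that real tumor data are
free of those artifacts.

## Numerical and degenerate-input choices

Zero-depth entries become missing CAF, never 0 — a fabricated 0 would look
like LOH. Sites with fewer than 3 usable samples or zero SD are excluded
from Z-scores and reported. Constant genes are skipped (not failed) by the
correlation screen and excluded from the BH adjustment. The enrichment
binomial is exact up to $10^4$ genes and a continuity-corrected normal
approximation above, with the method echoed in the result. Tail
probabilities are computed in log space, so "p < 1e-300" regimes stay
finite as log10 values. Whole-chromosome mask intervals use a fixed end
sentinel of $2^{29}$ bp (longer than any mouse chromosome) so the mask is
valid BED without a genome file. All writers emit fixed column orders and
the generator is seeded through `withr::with_seed`, making every output
byte-reproducible.

## A caveat on the Poisson/binomial null

The zero-outlier expectation $e^{-nr}$ treats the $n$ flags of a gene as
independent. Include-self studentization violates this within a site: with
20 samples, $\sum_i Z_i^2 = 19$, so one extreme value suppresses the others
and, conversely, some value is quite likely to sit near the $|Z| = 2$
boundary. In an event-free simulation at depth 10,000 the per-entry flag
rate matches an independent Monte-Carlo oracle (≈ 0.043, the internally
studentized tail, not the Gaussian 0.0455), but the fraction of
zero-outlier genes (≈ 0.02–0.03 with 3 sites per gene) is well below the
independence prediction at the measured rate (≈ 0.07). The package tests
document this bias; the practical consequence is that the analytic null
*understates* how many genes should show at least one outlier by chance,
so enrichment p-values against it are anti-conservative and are best read
as descriptive of a strong excess rather than as calibrated tail
probabilities.

## Problem sizes used by the tests

The default test suite runs on reduced cohorts (10–20 tumors, 150–5,000
sites) chosen to keep every stochastic check stable under its fixed seed:
simulator calibration uses 5,000 sites; the null-calibration check uses
5,000 sites × 20 tumors against a $10^5$-site Monte-Carlo oracle; oracle
equivalence uses 200 random instances of up to 10 sites × 20 samples; and
recovery checks run the full default cohort (11,700 sites) with shift 0.4
at depth 200. All expected values are either analytic, hand-computed, or
produced by independent brute-force reimplementations kept in the test
helpers.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_ase(sim_config(seed = 1))
dir <- tempfile()
paths <- write_sim(sim, dir)

res <- run_vloh(vloh_config(
  variants = paths[["variants"]],
  counts = paths[["counts"]],
  expression = paths[["expression"]],
  out_dir = file.path(dir, "results"),
  seed = 1
))
print(res)

glance(res$calls)
tidy(res$correlations) |> arrange(p) |> head()
plot_variegation(res$calls, "chr10")
```

## Known limitations

* The concerted-LOH scan judges skew on mean CAF; a chromosome skewed in
  opposite directions in different tumors (the X under random
  X-inactivation) is balanced on site means and is handled by the
  unconditional chrX mask instead.
* The correlation screen assumes an approximately linear
  burden–expression relationship; `method = "spearman"` relaxes this at
  some power cost.
* Sensitivity figures from the simulator assume gene-level cis events that
  shift all of a gene's sites together; single-site events are diluted by
  the gene-level aggregation rule.
* The 1-in-20 nominal outlier rate and the 1% chance-correlation rate are
  modeling assumptions inherited from the analysis design, not estimates;
  both are parameters.
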