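---
title: "Deconvolving cell-type-specific signals from mixed-cell sputum omics"
author: "sputodeconv authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvolving cell-type-specific signals from mixed-cell sputum omics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sputodeconv)
```

## The problem

Induced sputum is a mixture of immune and epithelial cells — alveolar
macrophages (AM), neutrophils (NG), eosinophils (EO), lymphocytes (LY),
monocytes (MO), ciliated cells (CC) and squamous cells (SC) — whose relative
abundance varies enormously between subjects and between disease groups.
Any bulk ("mixed-cell") expression or methylation measurement therefore
confounds two things: how much of each cell type a sample contains, and what
each cell type's molecular program looks like. A gene called "upregulated in
asthma" on mixed-cell data may simply mark eosinophilia.

`sputodeconv` separates these by regressing the mixed-cell signal on the
differential cell count, which is routinely recorded in sputum studies. For
feature $p$ and the samples of one group, the model is

$$ y_{ps} = \sum_{c \in \mathrm{majors}} f_{cs}\,\beta_{pc}
           + f_{\mathrm{other},s}\,\beta_{p,\mathrm{other}}
           + \varepsilon_{ps}, $$

where $f_{cs}$ are the counted cell fractions (rows renormalized to the unit
simplex after excluding monocytes, which are too scarce to estimate),
$\beta_{pc}$ is the latent cell-type-specific signal, and the summed minor
cell types enter as a single "weighed intercept" column, preserving residual
degrees of freedom. The fit is per feature by least squares under box
constraints — methylation estimates in $[0,1]$, expression estimates within
the array's dynamic range — because an unconstrained fit happily produces
negative expression or beta values above 1 for scarce cell types. This makes
every per-feature fit a small quadratic program.

## The solver

For the designs that occur here ($p \le 6$ coefficients) the QP is solved
exactly: the unconstrained ordinary-least-squares solution is computed first
and returned when it is interior to the box (the common case); otherwise
every assignment of coefficients to {free, at lower bound, at upper bound}
is enumerated, each equality-constrained subproblem solved in closed form,
and the best feasible candidate returned. Because the true optimum's active
set is one of the enumerated configurations, the result is exact rather than
iterative. The test suite checks this against two independent oracles:
closed-form OLS on interior instances (agreement to 1e-8 over 1000 random
problems) and an exhaustive $10^{-3}$-step grid over $[0,1]^2$ on exterior
instances (the QP objective never exceeds the best grid point over 200
problems).

Standard errors use the standard regression formula
$\widehat\sigma^2 = \mathrm{RSS}/(n-p)$,
$\mathrm{SE}_j = \widehat\sigma \sqrt{[(F^\top F)^{-1}]_{jj}}$, with
residual degrees of freedom $n-p$ shared by all coefficients of a feature.
This formula ignores active box constraints — a deliberate, documented
approximation; features with active constraints are flagged
(`nActive > 0`) so users can filter them. Near-singular designs receive a
tiny ridge (1e-8 on the diagonal of $F^\top F$) with a warning rather than
failing a long run.

Group comparisons of the estimates use a Welch unequal-variance $t$ test
built from the estimates and their SEs,
$t = (b_1-b_2)/\sqrt{se_1^2+se_2^2}$ with Welch–Satterthwaite degrees of
freedom. Because the estimate distributions likely violate normality, the
significance policy on deconvolved data is deliberately strict: BH-adjusted
$p < 0.001$ with $|\Delta\beta| \ge 0.1$ for methylation, $p < 0.005$ with
$|\log_2\mathrm{FC}| \ge 1.5$ for expression (mixed-cell screens use
BH $p < 0.05$ at the same effect cutoffs).

## RNA degradation and its correction

Long-term biobank storage degrades RNA; the RNA integrity number (RIN)
quantifies it. Degradation acts multiplicatively on linear intensities, so
the generator models probe $p$ in sample $s$ as retaining
$2^{-\lambda_p (\mathrm{RIN}_{\mathrm{ref}} - \mathrm{RIN}_s)}$ of its
signal, with probe-specific decay rates $\lambda_p \ge 0$. After rank-based
quantile normalization, overall signal loss is redistributed: fast-decaying
probes end up positively correlated with RIN and stable probes negatively —
a counterintuitive sign-mixed correlation spectrum that the generator
reproduces and the tests assert (at least 10% of probes on each side).

Two corrections are provided. *Correlation filtering* drops probes whose
$|r|$ with RIN exceeds a threshold; the threshold is a required explicit
parameter because it trades transcript coverage against residual bias and
has no universal value. *Linear correction* fits, per probe, an intercept
plus RIN slope (optionally plus group indicators) and subtracts only the
RIN term, relative to a reference RIN (default: cohort mean, keeping values
on the observed scale). In covariate-free mode the least-squares residual
property makes every probe's post-correction correlation with RIN
numerically zero. When degradation is confounded with group — the realistic
situation, since preservation chemistry differs between cohorts — the
covariate-free fit absorbs part of the true group effect into the RIN
slope; the group-covariate mode exists precisely for that case and is what
the confounded-scenario tests use. Samples with RIN below 3 are rejected at
intake (configurable).

## What the synthetic generator emulates

Every stage is validated against a generator with known ground truth, so no
download is needed. Its defaults are the study conditions of the motivating
cohort:

* **Cell fractions.** Per-group Dirichlet distributions with mean vectors
  set to the published differential counts (asthma AM/NG/EO/LY/MO/CC/SC =
  27.9/54.7/12.9/0.7/0.1/1.6/2.1%; COPD 9.0/88.9/1.0/0.2/0.0/0.4/0.6%;
  controls 52.3/40.3/0.2/2.0/0.2/1.6/3.4%) and a single concentration per
  group (3.2 / 21 / 3.0) chosen so the marginal SDs of the dominant cell
  types approximate the published ones. A Dirichlet guarantees valid
  simplex rows; the cost is that no single concentration can also reproduce
  the very large published eosinophil SD in asthma (a bimodal T2-high /
  T2-low mix), so individual small-$n$ draws can realize less EO variance
  than the cohort showed — which is exactly when deconvolution of EO is
  genuinely hard.
* **RIN.** Truncated normals per preservation route: RLT buffer
  8.6 ± 0.4 on [7.6, 9.1]; HOPE fixation 4.3 ± 0.6 on [3.2, 5.1]. By
  default preservation is confounded with group (COPD samples are mostly
  HOPE-preserved), as in the cohort.
* **Degradation.** Half of the probes are susceptible with exponential
  rates, mean $\lambda = 0.3$ log2 units per RIN unit — calibrated so that
  degradation dominates the first principal component of an uncorrected
  study (the situation that motivates correction); at much smaller rates
  degradation is a minor variance component and correction is moot.
* **Profiles and effects.** Per-cell-type expression (log2 baseline
  uniform on [6, 12], linear dynamic range [1, 65536]) and methylation
  (bimodal Beta(0.5, 0.5) baseline) profiles, with marker features and
  spiked group effects (log2FC 1.5; $\Delta\beta$ 0.2) on major cell
  types. Effects that would leave the valid range are clipped and the
  truth tables record the *achieved* effect — a boundary-clipped spike with
  achieved $|\Delta\beta| < 0.1$ is, by definition, not a true DMP at the
  published effect cutoff.
* **Plumbing for the full pipeline.** Agilent-style probe flags with
  planted per-rule drop sets, technical replicate probes, CpG genomic
  positions laid out so spiked DMPs form mergeable runs, sex-chromosome /
  SNP / cross-reactive / detection-failure CpGs, synthetic gene models
  tiling the CpG layout, and gene sets (GMT) including one set seeded with
  true DMR genes.

What the generator does **not** emulate: probe sequences and hybridization
chemistry, raw IDAT/scan files, spatial array artifacts, correlated
biological covariation between features, or cell-type fraction measurement
error in the differential count itself. Passing tests therefore demonstrate
correctness of the algorithms under the stated statistical model, not
performance on any particular real data set.

## Numerical choices

* Quantile normalization assigns ties the mean of the tied rank values
  (deterministic and order-independent); it is idempotent to 1e-12 and
  rank-preserving within columns, both asserted.
* Background correction ("minimum" convention): nonpositive
  background-corrected values are replaced by half the minimum positive
  corrected value of the same array.
* The detection-p rule defaults to "fail in any sample drops the CpG", with
  a fraction-based alternative (`mode = "fraction"`).
* PCA component signs are fixed by making the largest-magnitude loading
  positive; rank-deficient requests are reduced with a warning.
* Genomic intervals are held as 1-based closed `GRanges` internally (the
  Bioconductor convention); BED output converts to 0-based half-open at the
  boundary. Promoters are 1500 bp upstream of the strand-appropriate TSS,
  clipped at position 1; region–gene assignment requires ≥ 200 bp overlap.
* The DMR caller is a transparent merge rule (consecutive significant CpGs
  within 1000 bp, ≥ 2 CpGs, at least one CpG with $|\Delta\beta| > 0.1$) —
  a deliberately simple substitute for kernel-based region statistics,
  which are out of scope.
* Welch tests guard degenerate variances: both groups constant and equal
  gives $t = 0, p = 1$; constant but unequal gives an underflow-guarded
  near-zero $p$.

## Problem sizes used in validation

The shipped test-suite and acceptance-script scenarios use 10 samples per
group and 2000 features per modality (5000 for the sign-mixing property),
1000 + 200 random instances for the solver oracles, and 10000 features for
null-calibration checks. These sizes were chosen as the smallest at which
the checked properties are statistically stable; all of them are
configuration parameters, and nothing in the implementation depends on
them.

## A worked example

```{r example, eval = FALSE}
library(sputodeconv)

study <- simulateSputumStudy(sputumStudyConfig(), seed = 1)

# deconvolve asthma methylation on counted fractions
gs  <- study$samples$sample_id[study$samples$group == "asthma"]
des <- buildDesign(study$fractions[study$fractions$sample_id %in% gs, ],
                   majorTypes = c("AM", "NG", "EO"), excluded = "MO")
est <- deconvolveGroup(study$methylation[, gs], des, group = "asthma")
est

# how close are the estimates to the planted truth?
truth <- study$profiles$methylation$asthma
mean(abs(estimates(est)[, "AM"] - truth["AM", rownames(estimates(est))]))
```

Or run everything at once from the committed demo configuration:

```{r pipeline, eval = FALSE}
cfg <- readRunConfig(system.file("extdata", "demo.yaml",
                                 package = "sputodeconv"))
manifest <- runPipeline(cfg, "demo-out")
names(manifest$stages)
```

## Known limitations

* SEs ignore active box constraints; heavily constrained features carry
  optimistic SEs and are flagged rather than corrected.
* Cell types that are scarce or show little fraction variance within a
  group (lymphocytes everywhere; macrophages in COPD, mean 9%) cannot be
  estimated reliably — their SEs inflate, which the identifiability-ladder
  test demonstrates, but no amount of modeling recovers information the
  design does not contain.
* The mixed-cell Welch test is a simple substitute for moderated
  empirical-Bayes statistics; with small groups it is conservative.
* Fold changes on deconvolved expression are ratios of linear-scale
  estimates (`log2(b1/b2)`); a difference-of-relogged-values alternative
  would differ for features near the lower bound.
* The deconvolution assumes counted fractions are exact; differential-count
  error propagates into the estimates unmodeled.
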