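# sputodeconv

Cell-type deconvolution and RNA-degradation correction for mixed-cell
sputum omics.

Induced sputum contains a highly variable mixture of cells — alveolar
macrophages (AM), neutrophils (NG), eosinophils (EO), lymphocytes,
monocytes, ciliated and squamous cells — so bulk expression or methylation
profiles of asthma and COPD sputum confound cellular composition with
cell-intrinsic regulation, and long biobank storage adds RNA-degradation
bias on top. `sputodeconv` is for respiratory researchers who have
mixed-cell array matrices plus routine differential cell counts and want
cell-type-level answers without physical cell sorting.

## The core method

For each feature `p` within one sample group, the mixed-cell signal is
modeled as a fraction-weighted sum of latent cell-type profiles,

    y_ps = sum_c f_cs * beta_pc + f_other,s * beta_p,other + e_ps

with the counted cell fractions `f` (renormalized to the simplex after
excluding monocytes) as predictors and the summed minor cell types as a
"weighed intercept". Each per-feature fit is solved as a box-constrained
least-squares problem — a quadratic program — so methylation estimates stay
in [0, 1] and expression estimates inside the array's dynamic range. The
solver is exact (OLS fast path plus active-set enumeration) and is verified
in the test suite against closed-form OLS and an exhaustive-grid oracle.
Standard errors follow the usual regression formula with n − p residual
degrees of freedom; groups are compared with Welch unequal-variance t tests
on the estimates, under deliberately strict cutoffs (BH p < 0.001,
|Δβ| ≥ 0.1 for methylation; BH p < 0.005, |log2FC| ≥ 1.5 for expression).

Around that core: array preprocessing (background correction, quantile
normalization, flag/annotation filtering, replicate averaging), RIN-bias
diagnosis and correction (correlation filtering or per-probe linear
regression, PCA diagnostics), mixed-cell differential analysis, DMP-to-DMR
merging with promoter/gene-body mapping, hypergeometric gene-set
enrichment with custom backgrounds, and a fully parameterized synthetic
study generator with known ground truth.

## A worked example

```r
library(sputodeconv)

study <- simulateSputumStudy(sputumStudyConfig(), seed = 1)

gs  <- study$samples$sample_id[study$samples$group == "asthma"]
des <- buildDesign(study$fractions[study$fractions$sample_id %in% gs, ],
                   majorTypes = c("AM", "NG", "EO"), excluded = "MO")
est <- deconvolveGroup(study$methylation[, gs], des, group = "asthma")
est
#> CellProfileEstimate [asthma, methylation-beta]: 2000 features x 4 coefficients (AM, NG, EO, other)
#>   bounds [0, 1]; 685 features with active box constraints

truth <- study$profiles$methylation$asthma
mean(abs(estimates(est)[, "AM"] - truth["AM", rownames(estimates(est))]))
#> [1] 0.0225479
```

The mean absolute error of the macrophage beta estimates against the
planted truth is about 0.023 beta units at the default noise level — i.e.
the deconvolution recovers the latent cell-type methylation profile to
within a few percent, from ten mixed samples and their cell counts alone.
Features whose fit hit a box bound are flagged (`nActive > 0`) because
their standard errors are approximate.

The full pipeline (simulate → preprocess → RIN-correct → deconvolve →
differential → regions/enrichment) runs from one YAML config:

```r
cfg <- readRunConfig(system.file("extdata", "demo.yaml",
                                 package = "sputodeconv"))
manifest <- runPipeline(cfg, "demo-out")
names(manifest$stages)
#> [1] "simulate"     "preprocess"   "rincorrect"   "deconvolve"
#> [5] "differential" "regions"
```

`manifest.json` records the config hash, seed and MD5 of every output, so
a rerun with the same config and seed is bit-identical. A thin CLI wrapper
lives at `inst/scripts/sputodeconv.R`.

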