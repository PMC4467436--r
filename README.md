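# coexsig

Targeted, seed-gene coexpression analysis of tumor expression profiles,
built for the glioblastoma (GBM) setting in which surface-marker genes such
as CD133 (*PROM1*) and CD44 anchor transcriptional programs that track the
Proneural (PN) and Mesenchymal (MES) molecular subtypes. The package is for
computational biologists who want to go from a gene × sample expression
matrix (plus optional clinical and mutation tables) to marker coexpression
modules, per-sample module scores, a dichotomous subtype call, pathway
enrichment of the marker-correlated genes, and subtype-specific treatment
hazard ratios — with every stage testable against a synthetic cohort with
planted ground truth.

## What it computes

**Module discovery.** For a seed gene *s*, every gene *g* gets the Pearson
(or Spearman) correlation *r<sub>g</sub>* with *s* over pairwise-complete
samples, a two-sided p-value from
*t = r√((n−2)/(1−r²))* on *n−2* df, and a Benjamini–Hochberg q-value. The
coexpression module is

&nbsp;&nbsp;&nbsp;&nbsp;{ *g* : *r<sub>g</sub>* > mean(*r*) + 2·sd(*r*),
 *q<sub>g</sub>* < 0.05, *r<sub>g</sub>* > 0 },

with the empirical percentile of the cutoff reported alongside.

**Single-sample scoring (GSVA-style).** Expression is transformed per gene
to its empirical cdf across samples; within each sample, genes are ranked
by decreasing transformed value and given the symmetric weight
|N/2 − rank|. A weighted Kolmogorov–Smirnov random walk over the ranked
genes (members step up by their normalized weight, non-members step down by
1/(N−m)) yields the enrichment score ES = D⁺ + D⁻, the signed difference of
the largest positive and negative walk deviations. Each sample is labelled
by the module with the greater ES (argmax over candidates, winning margin
reported).

**Inference.** The rank-sum, hypergeometric-overlap, binomial, Fisher's
exact, and Welch *t* tests plus BH-FDR are implemented in the package (exact
enumeration for small samples, log-space combinatorics so overlap p-values
far below 1e-100 remain meaningful) and cross-checked in the test suite
against independent enumeration oracles and base R.

**Preranked GSEA.** Marker correlation profiles, ranked, are tested against
gene-set collections (GMT) with the classic weighted walk, a gene-set
permutation null, NES = ES / mean(|same-sign null ES|), add-one nominal
p-values, and the pooled null-ratio FDR.

**Survival.** Kaplan–Meier product-limit curves with Greenwood standard
errors, the k-group log-rank test, and a Cox proportional-hazards fitter
(Efron tie handling, damped Newton–Raphson, Wald 95% CIs, divergence
detection) with predicted survival curves at covariate means and a
per-subtype treatment-effect report (age, G-CIMP, radiotherapy,
temozolomide).

**Synthetic cohorts.** `sim_config()` plants coexpression modules via a
latent-factor construction (*x = √ρ·f + √(1−ρ)·e*) whose member–member
correlation is analytically ρ, subtype-dependent module activation,
exponential survival with subtype×treatment log hazard ratios, and
subtype-enriched binary mutations — all byte-reproducible from one seed.

## Worked example

Simulate a 300-tumor cohort with mirrored CD133-like/CD44-like programs and
a radiotherapy benefit planted only in the PN-like subtype, then run the
full discovery → scoring → classification → survival chain:

```r
library(coexsig)
cfg <- sim_config(
  n_genes = 1000, n_samples = 300,
  modules = list(
    planted_module("CD133-M", "PROM1", 50, 0.8, c(PN = 1,  MES = -1)),
    planted_module("CD44-M",  "CD44",  50, 0.8, c(PN = -1, MES = 1))),
  subtype_proportions = c(PN = 0.5, MES = 0.5),
  survival = list(treatment_log_hr = data.frame(
    subtype = "PN", treatment = "radiotherapy", log_hr = -1.25)),
  rng_seed = 42)
sim  <- simulate_expression(cfg)
mod  <- select_module(correlate_with_seed(sim$expression, "PROM1"))
mod
#> Coexpression module for seed 'PROM1': 49 genes
#>   cutoff: mean + 2 SD (r > 0.4785, 95.1 percentile), q < 0.05, positive only
```

The 2-SD cutoff lands at the 95.1st percentile of the correlation profile
and recovers the planted 50-gene program (49 members; the seed itself is
excluded by design). Scoring and classification:

```r
mods <- list("CD133-M" = mod,
             "CD44-M"  = select_module(correlate_with_seed(sim$expression, "CD44")))
es <- score_samples(sim$expression, mods)
cl <- classify(es, c("CD133-M", "CD44-M"))
table(call = cl$label, truth = sim$truth$sample_subtype)
#>          truth
#> call      MES  PN
#>   CD133-M   7 146
#>   CD44-M  139   8
```

285/300 samples recover their planted program (95%; the latent-factor
model bounds what any classifier can do here — see the methods vignette).
Per-subtype treatment effects:

```r
clin <- simulate_clinical(cfg, sim$truth)
res  <- subtype_treatment_analysis(clin, setNames(cl$label, cl$sample))
res$table
#>   subtype    treatment    hr ci_lower ci_upper        p
#> 1  CD44-M radiotherapy 0.803    0.559    1.153 2.34e-01
#> 2  CD44-M temozolomide 0.932    0.649    1.338 7.02e-01
#> 3 CD133-M radiotherapy 0.227    0.150    0.344 2.56e-12
#> 4 CD133-M temozolomide 1.380    0.953    1.999 8.86e-02
```

The planted radiotherapy benefit (true HR e^−1.25 ≈ 0.29) is recovered in
the CD133-M stratum (HR 0.227, 95% CI 0.150–0.344) while the CD44-M
confidence intervals cover 1, mirroring the Table-3-style report the
pipeline emits. `run_all(pipeline_config(...))` drives the same chain from
files on disk (TSV/GCT expression, GMT gene sets, clinical TSV) and writes
every stage's tables plus a checksummed run manifest.

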