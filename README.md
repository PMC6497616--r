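# mrflow

Two-sample Mendelian randomisation (MR) from GWAS summary statistics, in
R. The package grew out of the question of whether higher weight at birth
causally increases adult breast-cancer risk — an association repeatedly
reported by observational studies — but every component is generic: it is
aimed at epidemiologists and statistical geneticists who have per-SNP
summary tables for an exposure and an outcome from non-overlapping GWAS
and want the full modern MR workflow with its sensitivity analyses,
diagnostics and power analytics, verifiable end to end on simulated data
with known causal truth.

## What it computes

For SNP *j*, with exposure association β̂_Xj (SE σ_Xj) and outcome
association β̂_Yj (SE σ_Yj) both oriented to the exposure-increasing
allele, the per-SNP Wald ratio is θ̂_j = β̂_Yj / β̂_Xj with first-order SE
σ_Yj / |β̂_Xj|. On an instrument of L such SNPs the package provides:

- **IVW**: θ̂ = Σ w_j β̂_Xj β̂_Yj / Σ w_j β̂_Xj², w_j = 1/σ_Yj², with
  multiplicative random-effects SE inflation max(1, √(Q/(L−1)));
- **MR-Egger**: the same regression with a free intercept (average
  directional pleiotropy; t test on L−2 df);
- **weighted median** (valid if >50% of weight is valid) and **weighted
  mode** (valid if the largest cluster of similar ratios is valid), with
  parametric-bootstrap SEs;
- **penalised robust IVW**: heterogeneity-penalised weights
  w_j·min(1, 20 p_j) plus a Tukey-bisquare MM regression;
- **diagnostics**: Cochran's Q with per-SNP contributions, greedy stepwise
  Q pruning, Cook's distance (threshold 4/L), leave-one-out, studentised
  residuals (±2);
- **multivariable MR** (joint regression on K exposures' betas) and its
  Egger extension;
- **instrument strength and power**: variance explained from p/n or from
  allele frequencies, F = (r²/(1−r²))·((n−k−1)/k), and binary-outcome
  power Φ(|ln OR|·√(N r² φ(1−φ)) − z_{1−α/2});
- **harmonisation**: allele alignment, proxy-SNP substitution by r²
  threshold, pleiotropy filtering against covariate traits, full
  provenance logging; and
- **a synthetic two-sample generator** with configurable causal effect and
  pleiotropy architecture (balanced, directional, InSIDE-violating), whose
  defaults emulate a 41-SNP instrument explaining ~1.3% of a standardised
  exposure (F ≈ 46) against an outcome GWAS of 122,977 cases and 105,974
  controls.

## Worked example

```r
library(mrflow)

# a synthetic study at the default scale with true OR 0.86 per SD exposure
spec <- syntheticStudySpec(theta = log(0.86), seed = 42)
set <- simulateInstrumentSet(spec)$set

est <- mrEstimate(set, nBoot = 1000, seed = 1)
estimatesTable(est, ivSet = "synthetic41", outcome = "overall")
```

```
               method n_snps    or or_lower or_upper   pvalue
                  IVW     41 0.850    0.792    0.912 5.62e-06
             MR_Egger     41 0.882    0.683    1.139 3.42e-01
      weighted_median     41 0.862    0.784    0.947 2.03e-03
        weighted_mode     41 0.885    0.765    1.024 1.01e-01
 IVW_penalised_robust     41 0.859    0.801    0.921 2.08e-05
```

All five estimators sit near the planted odds ratio of 0.86 per 1-SD
exposure; MR-Egger's interval is widest because its slope only uses the
spread of the exposure effects. Heterogeneity and instrument strength:

```r
cochranQ(set)
#> Cochran's Q = 23.028 on 40 df, p = 0.986

fStatistic(0.013, 143677, 41)
#> F = 46.1 (weak-instrument flag FALSE)

binaryOutcomePower(0.013, 122977, 105974, 1.06)
#> 0.35
```

The last two lines say: an instrument explaining 1.3% of the exposure in
a GWAS of 143,677 is strong (F ≈ 46, well above the weak-instrument bound
of 10), but has only 35% power to detect an odds ratio of 1.06 per SD in
an outcome sample of ~229k — small true effects can escape such a study.

A full analysis (harmonise → filter → estimate → diagnose → MVMR → power)
runs from one YAML config via `runPipeline()`; `reproduceSupplement()`
re-analyses curated per-SNP tables (e.g. a published study's
supplementary tables exported to TSV), including the pruned-instrument
and multivariable stages. A positive-control workflow — confirming that
the same instrument recovers the established association between lower
birth weight and type 2 diabetes (IVW OR ≈ 1.9 per 1-SD lower birth
weight) — is supported the same way once the corresponding T2D summary
statistics are supplied; they are external data and are not
redistributed.

See `vignettes/two-sample-mr.Rmd` for the models, assumptions, numerical
choices and known limitations.

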