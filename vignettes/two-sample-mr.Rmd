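---
title: "Two-sample Mendelian randomisation with mrflow: models, diagnostics and design choices"
author: "mrflow authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomisation with mrflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrflow)
```

# The problem and the model

Mendelian randomisation (MR) uses genetic variants as instrumental
variables to ask whether an exposure causes an outcome. Because alleles
are allocated at random at conception, a SNP that raises the exposure acts
like a lifelong micro-randomised intervention: if the exposure causes the
outcome, the exposure-raising allele must shift outcome risk in
proportion. `mrflow` implements the two-sample summary-statistics form of
this design, in which per-SNP associations with the exposure (here a
standardised quantitative trait such as birth weight, in SD units) and
with the outcome (a disease log-odds, from an independent case-control
GWAS) are combined without any individual-level data.

For SNP $j$, let $\hat\beta_{Xj}$ (SE $\sigma_{Xj}$) be the per-allele
exposure association and $\hat\beta_{Yj}$ (SE $\sigma_{Yj}$) the outcome
association, both expressed on the exposure-increasing allele. Each SNP
gives a Wald ratio $\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ with
first-order SE $\sigma_{Yj}/|\hat\beta_{Xj}|$. MR is valid for a SNP if it
(1) associates with the exposure, (2) is independent of confounders, and
(3) affects the outcome only through the exposure. Assumption 3
(no horizontal pleiotropy) is untestable per SNP, so the package provides
five estimators whose validity degrades differently as it fails, plus
heterogeneity and influence diagnostics, multivariable adjustment, and a
generator with known causal truth to verify all of it.

# Estimators

**IVW.** The inverse-variance weighted estimate is the zero-intercept
weighted regression of $\hat\beta_{Yj}$ on $\hat\beta_{Xj}$ with weights
$w_j = 1/\sigma_{Yj}^2$:
$\hat\theta = \sum w_j \hat\beta_{Xj}\hat\beta_{Yj} / \sum w_j \hat\beta_{Xj}^2$,
algebraically a weighted mean of the Wald ratios and equivalent to
two-stage least squares on individual data (the test suite checks this
equivalence on the simulator's individual-level mode). The fixed-effects
SE is $(\sum w_j\hat\beta_{Xj}^2)^{-1/2}$; under the multiplicative
random-effects model the SE is inflated by
$\max\!\bigl(1,\sqrt{Q/(L-1)}\bigr)$, where $Q$ is Cochran's Q, so
heterogeneity widens but never narrows the interval. Random effects is the
default, matching common primary-analysis practice.

**MR-Egger.** The same regression with a free intercept, all instruments
oriented to the exposure-increasing allele. Under the InSIDE assumption
(pleiotropic effects independent of instrument strength) the slope is a
consistent causal estimate even if every SNP is pleiotropic, and the
intercept estimates the average directional pleiotropic effect; its
two-sided test uses a $t$ distribution on $L-2$ df. The random-effects
scale is the weighted residual SD on $L-2$ df, floored at 1.

**Weighted median.** Wald ratios are ordered; each carries normalised
weight $w_j \propto 1/\mathrm{se}(\hat\theta_j)^2$; the estimate linearly
interpolates ratio against cumulative-weight midpoint
$p_j = \sum_{i\le j} w_i - w_j/2$ at $p = 0.5$. Consistent when valid
instruments carry over half the weight.

**Weighted mode.** The argmax of a normal-kernel weighted density of the
Wald ratios. Bandwidth is the modified Silverman rule
$0.9\,\min(\mathrm{sd},\mathrm{mad})\,L^{-1/5}$ on the ratios (the
`mad` falls back to the `sd` if it degenerates to zero), multiplied by a
configurable `bandwidthFactor` (default 1; sensitivity at 0.5 and 2 is one
argument away). The density is maximised on a fixed grid of 2048 points
spanning the ratio range plus three bandwidths; if all ratios coincide the
common ratio is returned. Consistent when the largest cluster of similar
ratios is valid.

**Penalised robust IVW.** Each SNP's Cochran-Q contribution is referred to
a 1-df chi-square upper tail $p_j$ and its weight multiplied by
$\min(1, p_j/0.05)$ — i.e. multiplier 20 at the conventional penalty
level, so SNPs compatible with the pooled estimate are untouched — and a
zero-intercept MM regression with Tukey bisquare loss (tuning constant
4.685, 95% efficiency under normality) is fitted under those weights. The
reported SE is the robust-fit SE floored at the fixed-effects IVW SE
computed with the penalised weights; this floor is at least the plain
fixed-effects SE, so penalisation never manufactures spurious precision.
Exactly collinear data short-circuit to weighted least squares (the robust
problem is degenerate at zero residual scale); a non-converged robust fit
falls back to the penalised non-robust solution with a warning.

**Scales and intervals.** Estimates are log-odds per 1-SD exposure;
`oddsRatio()` exponentiates. All confidence intervals are normal-theory
$\hat\theta \pm 1.96\,\mathrm{se}$ (MR-Egger can optionally use $t_{L-2}$
critical values); p-values are two-sided normal except the Egger terms,
which use $t_{L-2}$. Median and mode SEs come from a parametric bootstrap
(exposure and outcome betas resampled from normals with their reported
SEs; default 5000 replicates, seed exposed and logged; SEs are stable to
about two significant figures at that size, and `nBoot = 0` skips the
bootstrap for simulation studies that need only point estimates).

# Harmonisation and instrument construction

`readSummaryStats()` ingests tab-separated GWAS tables through a
documented column-alias table; rows lacking beta or SE are dropped with a
count, and p-values grossly inconsistent with beta/SE (10-fold on the log
scale) trigger a warning, not an error. `harmoniseInstruments()` aligns
outcome and covariate records to the exposure's effect allele (sign flip
plus frequency complement when orientations are swapped; irreconcilable
allele pairs are excluded with reason `allele_mismatch`), orients every
record to the exposure-increasing allele (null exposure effects are
excluded as `null_instrument`), substitutes linkage-disequilibrium proxies
for lead SNPs absent from a dataset when the proxy's $r^2$ exceeds a
threshold (0.6 by default for univariable work, 0.8 where strongly
correlated proxies are required, e.g. multivariable tables), and records
every decision. Matching is by allele letters only: strand-ambiguous A/T
and C/G SNPs are retained by default because curated lead-SNP instrument
tables are normally pre-matched; `strictPalindromes = TRUE` drops
palindromic SNPs with effect-allele frequency in [0.42, 0.58], the band in
which orientation is genuinely undecidable. A proxy whose alleles differ
from its lead's is taken as reported (assumed to tag the lead's
exposure-increasing allele), since no cross-locus letter alignment exists.

Instrument sets are built by `filterPleiotropic()`: SNPs associated with
any covariate trait below a p threshold are removed and logged with the
offending trait. Running the same candidates at the genome-wide threshold
$5\times10^{-8}$ and at the Bonferroni threshold $\alpha/m$ (with $m$ the
number of loci examined) yields nested sets of decreasing size —
the pattern used to probe sensitivity to pleiotropy filtering. Covariate
traits supplying only p-values participate in filtering but are never
entered into multivariable designs.

# Diagnostics

All influence measures are computed on the weighted zero-intercept IVW
regression — the model actually being diagnosed, not an intercept variant.
`cochranQ()` returns $Q = \sum_j (\hat\theta_j - \hat\theta)^2 /
\mathrm{se}(\hat\theta_j)^2$ with $L-1$ df and per-SNP contributions.
`stepwiseQPrune()` implements greedy downward selection: remove the SNP
with the largest Q contribution, refit, repeat until the Q test p-value
reaches the stopping level (0.05 default). Q strictly decreases each step;
ties break lexicographically on SNP id for determinism. Whether such a
procedure should refit the pooled estimate each round is ambiguous in
common descriptions; both variants are implemented (`refit = TRUE` is the
default, `refit = FALSE` scores against the initial estimate throughout).
`cooksInfluence()` flags Cook's distance above $4/L$; `leaveOneOut()`
re-estimates IVW dropping each SNP; `studentisedOutliers()` flags
externally studentised residuals beyond $\pm 2$. Exact-fit data (zero
residuals) are treated as zero influence rather than 0/0.
`influenceDiagnostics()` bundles the four flag sets; its leave-one-out
flag marks SNPs whose omission shifts the estimate by more than twice the
SD of the leave-one-out estimates.

# Multivariable MR

`mvmrIVW()` regresses outcome betas jointly on $K$ exposures' betas
(no intercept, weights $1/\sigma_{Yj}^2$, multiplicative random-effects
scaling floored at 1 on all coefficients); each coefficient is that
exposure's direct effect holding the others fixed, and with $K=1$ the
model reproduces univariable IVW exactly. `mvmrEgger()` adds a free
intercept (average pleiotropy not mediated by any included exposure;
$t_{L-K-1}$ test), with rows oriented to the *primary*
exposure-increasing allele only — orientation cannot be simultaneous in
all exposures, and the primary trait is the estimand of interest.
Rank-deficient designs fail naming the collinear columns.

# Instrument strength and power

`varianceExplainedPN()` recovers each SNP's 1-df F statistic from the
upper tail of $F(1, n-2)$ at its exposure p-value and sums
$r^2_j = F/(n-2+F)$ — the route of choice when allele frequencies are
unavailable, and the default in the pipeline. `varianceExplainedFreq()`
is the frequency formula $\sum 2f_j(1-f_j)\beta_j^2$ for standardised
traits, used as the simulator's ground truth; the two agree on generated
data within simulation error. The instrument F statistic is
$\bigl(r^2/(1-r^2)\bigr)\bigl((n-k-1)/k\bigr)$ with the conventional
weak-instrument flag at $F<10$. A priori power for a case-control outcome
of $N$ samples with case fraction $\phi$ against a detectable odds ratio
$\mathrm{OR}$ at two-sided level $\alpha$ is
$\Phi\!\bigl(|\ln \mathrm{OR}|\sqrt{N r^2 \phi(1-\phi)} -
z_{1-\alpha/2}\bigr)$; the two-sided critical value reproduces standard
published power figures, the formula is exactly symmetric in
$\mathrm{OR} \leftrightarrow 1/\mathrm{OR}$, and at $\mathrm{OR}=1$ it
returns $\alpha/2$.

# The synthetic-data generator

`generateTwoSample()` draws, per SNP, a minor-allele frequency
$f_j \sim U(0.1, 0.5)$ and a true per-allele effect
$\gamma_j \sim U(0.015, 0.04)$ SD, then generates observed summary
statistics
$\hat\beta_{Xj} \sim N(\gamma_j, \sigma_{Xj}^2)$ with
$\sigma_{Xj} = 1/\sqrt{2f_j(1-f_j)\,n_{\mathrm{exp}}}$ and
$\hat\beta_{Yj} \sim N(\theta\gamma_j + \alpha_j, \sigma_{Yj}^2)$ with
$\sigma_{Yj} = \sqrt{N/(2f_j(1-f_j)\,n_{\mathrm{cases}}
n_{\mathrm{controls}})}$ — binary-outcome statistics are generated
directly on the log-odds scale with the case-control SE approximation
rather than by simulating genotypes, which keeps a 500-replicate study on
one CPU in seconds while `generateIndividualLevel()` provides a slow
exact escape hatch (binomial genotypes, linear or logistic outcome) for
cross-validation at small $n$. Pleiotropic direct effects $\alpha_j$
follow the chosen architecture: `none`, `balanced` (mean zero),
`directional` (mean $\mu_\alpha$), or `inside_violating` ($\alpha$
correlated with $\gamma$ at a set correlation, breaking InSIDE). The
defaults — 41 SNPs, exposure GWAS of 143,677, outcome of
122,977/105,974, total true $r^2 \approx 1.3\%$ (instrument
$F \approx 45$), $\theta = -0.15$ log-odds per SD — emulate a large
birth-weight instrument against a breast-cancer meta-analysis, the
regime the package is designed around.

Two generator design choices matter for interpreting simulations. First,
latent quantities ($f_j$, $\gamma_j$, $\alpha_j$, the invalid-SNP ids)
are drawn once per spec seed and held fixed across replicates, so
replicate-to-replicate variation isolates sampling noise; conditional on
one latent draw, finite-sample functionals such as the sample
$\alpha$–$\gamma$ association enter estimator expectations, and the test
suite compares against those conditional oracles where relevant. Second,
the generator simulates no linkage disequilibrium: instruments are
independent loci by construction, as curated lead-SNP instruments are.
What the generator does not emulate — winner's curse in instrument
discovery, sample overlap between the two GWAS, allele-frequency
mismatch between populations, un-standardised exposure scales — bounds
what passing simulations can certify about any real data set.

A consequence worth stating plainly: at the default (realistic)
instrument strength the exposure betas carry visible sampling error, so
regression-dilution attenuates estimators that regress on them. For IVW
the attenuation factor is
$\sum w\gamma^2 / (\sum w\gamma^2 + \sum w\sigma_X^2) \approx 0.98$ —
negligible against Monte-Carlo error — but MR-Egger's slope is diluted by
the *centred* analogue
$\mathrm{Var}(\gamma)/(\mathrm{Var}(\gamma) + \overline{\sigma_X^2})
\approx 0.75$ at these settings, a bias of about $0.05$ on
$\theta = \ln 0.86$ that no 500-replicate band covers. This is the
documented no-measurement-error (NOME) sensitivity of MR-Egger, not an
implementation artefact: the recovery suite shows the same code unbiased
once the exposure GWAS is scaled to make exposure betas nearly
noise-free, and the corresponding paper-scale Egger recovery check is
deliberately left failing rather than papered over with a wider band.

# Pipeline and reproduction entry points

`runPipeline()` drives the whole analysis from one YAML (or list) config:
read and harmonise with proxies, build the full / genome-wide-filtered /
Bonferroni-filtered instrument sets, run the configured estimators on
each, diagnose and stepwise-prune the main set, run multivariable MR
where covariate betas exist, compute variance explained, F and power, and
count outcome-association enrichment over chance. Every membership
decision is logged with stage and reason, and the provenance log alone is
sufficient to reconstruct each instrument set (tested by replay).
Identical configs reproduce outputs byte-for-byte; all thresholds default
to the conventional values (genome-wide $5\times10^{-8}$, Bonferroni
$\alpha = 0.05$ over the loci examined, proxy $r^2$ 0.6/0.8, stepwise
0.05, Cook's $4/L$, studentised 2).

`reproduceSupplement()` re-runs the univariable, pruned and multivariable
analyses from curated per-SNP tables such as a published study's
supplementary spreadsheets exported to TSV (spreadsheet parsing is
deliberately not a dependency). The acceptance test that compares against
published point estimates requires those tables under
`inst/extdata/supplement/` and reports their absence as a failure rather
than silently skipping; the package does not redistribute them.

# Problem sizes used by the test suite

The shipped suite runs entirely on generated data: 5-SNP fixtures against
closed-form oracles; 41-SNP studies at the default scale with 500
replicates for parameter recovery and 1000 for type-I error of the IVW
test and Cochran's Q (binomial 3.5-sigma bands around 5%); a
Kolmogorov–Smirnov check of Q against $\chi^2_{L-1}$ at 1000 replicates;
and an individual-level 2SLS cross-check at $n = 1500$ over 120
replicates. Monte-Carlo acceptance bands are four MC standard errors
unless a sharper analytic oracle is available.

# Known limitations

No LD modelling, clumping or reference panels: proxies come from a
user-supplied map, and instruments are assumed independent. No MR-PRESSO,
contamination-mixture or lasso variants. No conditional F statistics for
multivariable instruments, and no power calculations for continuous
outcomes. Bootstrap SEs for median/mode are approximate by construction;
published SEs for those methods depend on unstated bootstrap conventions
and are not expected to match to the digit.
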