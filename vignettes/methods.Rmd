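---
title: "Genetic-score Mendelian randomization: models, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic-score Mendelian randomization: models, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scoremr)
```

## The problem

Observational associations between body mass index (BMI) and breast-cancer
risk are entangled with confounding and reverse causation — in case-control
designs BMI is usually measured after diagnosis, when disease itself may have
changed body weight. Mendelian randomization (MR) side-steps both problems by
using genetic variants as instrumental variables: alleles are assorted at
meiosis independently of lifestyle confounders and decades before disease, so
the association of a BMI-predicting genotype with disease reflects (under the
instrumental-variable assumptions) the causal influence of BMI itself.

`scoremr` implements both MR designs used for this question:

* **One-sample**: individual-level genotype dosages, phenotypes and
  covariates in a single case-control consortium. A weighted genetic score
  is built, calibrated to BMI units, and regressed against case status.
* **Two-sample**: per-SNP summary statistics from a BMI GWAS (exposure) and
  an independent disease GWAS (outcome), combined per instrument with Wald
  ratios and across instruments by inverse-variance weighting (IVW), with
  Egger regression as a pleiotropy diagnostic.

## Models

### Genetic score and calibration

The raw score for individual $j$ is
$GS_j = \sum_{i=1}^{m} \beta_i \, d_{ij}$, with $\beta_i$ the per-allele BMI
effect (kg/m$^2$) from an external GWAS and $d_{ij} \in [0,2]$ the
effect-allele dosage. An unweighted variant ($\beta_i \equiv 1$) serves as a
sensitivity analysis. Because external weights place the score on an
arbitrary scale, observed BMI is regressed on $GS$ among **controls only**
(cases' post-diagnosis BMI is not a valid exposure measure), and the fitted
line $\hat\beta_0 + \hat\beta_1 GS$ is applied to every individual. The
calibrated score is a linear transform of the raw score — perfectly
correlated with it — so calibration changes the *units* of downstream odds
ratios (per kg/m$^2$ rather than per weight-unit) but not their z-statistics.

### One-sample analysis

Logistic regression of case status on the calibrated score with covariate
adjustment; odds ratios are reported per 5 kg/m$^2$, i.e. $e^{5\hat\beta}$.
The default covariate profile is age, eight genetic principal components and
study site; an extended profile adds reproductive and lifestyle risk
factors. Both pooled (site-adjusted) and meta-analytic (per-study fits
combined by fixed effects) summaries are available, along with stratified
fits (menopausal status, hormone-therapy use, ER/PR status) whose
between-stratum heterogeneity is tested with Cochran's Q on the stratum log
odds ratios — for two strata this is equivalent to a two-sample z-test.
Wald confidence intervals and p-values come from the observed information;
confidence intervals do not propagate calibration uncertainty (see
Limitations).

### Two-sample analysis

For a harmonized instrument with exposure effect $\hat\beta_{XG}$ (SE
$S_{XG}$) and outcome log-OR $\hat\beta_{YG}$ (SE $S_{YG}$), the Wald ratio
is $\hat\beta_{YX} = \hat\beta_{YG} / \hat\beta_{XG}$ with delta-method
standard error

$$ SE_{YX} \;=\; \sqrt{ \frac{S_{YG}^2}{\beta_{XG}^2}
   + \frac{S_{XG}^2\,\beta_{YG}^2}{\beta_{XG}^4} } . $$

A first-order mode drops the second term — the convention when the exposure
study is far larger than the outcome study, and the mode under which the
IVW estimate coincides algebraically with weighted least squares of
$\beta_{YG}$ on $\beta_{XG}$ through the origin. Per-instrument estimates
are combined by fixed-effects inverse-variance weighting; Cochran's Q
across instruments is reported as a heterogeneity diagnostic. Egger
regression fits $\beta_{YG} = a + b\,\beta_{XG}$ with weights $1/S_{YG}^2$
after orienting all instruments to $\beta_{XG} > 0$; a non-zero intercept
$a$ estimates the average directional (pleiotropic) direct effect, and the
slope is a pleiotropy-adjusted causal estimate. With the intercept
constrained to zero the Egger slope reproduces the first-order IVW estimate
exactly — exposed as a verification mode.

### Meta-analysis and printed-table recombination

Fixed-effects inverse-variance combination is used everywhere combination
is needed (per-study, per-stratum, cross-consortium); random-effects models
are deliberately omitted to keep the method surface minimal, and
inverse-variance weighting is associative, so meta-analyzing
meta-estimates equals meta-analyzing the pooled inputs. Published per-SNP
rows printed as "OR (95% CI)" are converted to the log scale by
$\beta = \ln OR$, $se = (\ln CI_{hi} - \ln CI_{lo}) / (2 z)$ before
recombination. Because printed inputs are rounded to two decimals, the
recombined ORs are expected to match printed combined ORs only to about
$\pm 0.01$; rows whose printed intervals are visibly asymmetric on the log
scale (an artifact of rounding) can shift by slightly more, and the bundled
17-SNP consortium fixture contains exactly one such row.

## Harmonization rules

Outcome records are aligned to the panel's effect allele: equal alleles
pass through, swapped alleles negate the outcome effect and reflect its
frequency, and complement matching is attempted (forward-strand assumption)
before a pair is declared incompatible. Palindromic SNPs (A/T, C/G) carry
no cross-strand allele information and are resolved by allele frequency:
by default they are dropped when either frequency lies in $[0.42, 0.58]$
and otherwise aligned so both frequencies fall on the same side of 0.5 —
the conservative community practice. Unmatched rsids are reported in a
structured attribute rather than silently discarded, since outcome GWAS
often lack a few instruments.

## The synthetic-data generator

The generator exists so every stage is testable end-to-end without access
to consortium individual-level data. It emulates, at desk scale, the
structure the analysis assumes:

* **Instruments**: 84 independent biallelic SNPs in Hardy-Weinberg
  equilibrium, EAF uniform on $(0.1, 0.9)$, non-palindromic allele pairs
  (a curated, strand-resolved panel). Effect magnitudes are drawn at or
  above the genome-wide-significance floor of the emulated discovery GWAS
  ($|\beta| \ge z_{5\times10^{-8}}\,se$ at $n \approx 339{,}000$) — real
  instrument panels are significance-selected, so true effects are bounded
  away from zero — then rescaled so the population score variance is
  exactly `r2_target` $\times$ `bmi_sd`$^2$ (default 1.23% of a 4.5
  kg/m$^2$ SD).
* **Exposure**: $BMI = \mu + \text{score} + \gamma_B U + \varepsilon$ with
  an unmeasured standard-normal confounder $U$ and noise variance chosen so
  the marginal SD equals `bmi_sd` (defaults $\mu = 26.5$, $\gamma_B = 1$).
* **Disease**: $\Pr(\text{case}) = \text{expit}(\alpha_0 + \theta\,BMI +
  \gamma_Y U + \sum_i \alpha_i g_i)$, with $\theta = \log(0.65)/5$ per
  kg/m$^2$ by default, $\gamma_Y = 0.2$, and $\alpha_0$ solved numerically
  so the population risk equals `prevalence` (default 0.10). The
  confounder affects both BMI and disease, so the naive BMI-outcome
  regression is biased while the genetic instruments remain valid — the
  pedagogical heart of the design. Optional directional pleiotropy injects
  direct effects $\alpha_i$ oriented relative to the exposure-raising
  allele (the frame in which the Egger intercept is defined).
* **Ascertainment**: cases are oversampled from the population to the
  target case fraction, which is how case-control marginal log-ORs arise;
  cases' observed BMI is masked by default, mirroring post-diagnosis
  measurement.
* **Covariates/strata**: age, eight standard-normal principal components,
  study site (5 sites by default), menopausal status (70% postmenopausal),
  hormone-therapy use among postmenopausal women, and ER/PR status among
  cases. These covariates are pure noise with respect to disease — they
  exercise the adjustment machinery without changing the estimand.

Reproducibility: one root seed; every operation (panel, genotypes,
phenotype noise, sampling, covariates) draws from its own derived
substream, so adding SNPs does not perturb phenotype draws and identical
configurations are byte-identical.

What the generator does **not** emulate: linkage disequilibrium between
instruments (the emulated panel is LD-pruned by construction), imputation
uncertainty beyond an optional fractional-dosage mode, genuine covariate
confounding structure (age and PCs do not influence disease), or
between-study effect heterogeneity. Passing tests therefore demonstrate
correctness of the estimators under the stated model, not robustness to
every failure mode of real consortium data.

## Numerical choices

* Confidence quantiles use `qnorm((1 + level)/2)` throughout (1.9599640 at
  95%), so OR↔log conversions round-trip exactly.
* Two-sided p-values are standard normal; no small-sample t corrections
  (instrument counts near 84 make them immaterial).
* Egger standard errors come from the weighted least-squares fit with its
  estimated residual scale (multiplicative over-dispersion), the usual
  convention for this regression.
* The logistic intercept of the disease model is found by `uniroot` on
  $[-40, 40]$; an unreachable target prevalence is a configuration error,
  reported as such.
* Missing dosages are imputed at their Hardy-Weinberg expectation
  $2 \times EAF$; individuals with all dosages missing get `NA` scores and
  a warning rather than a fabricated population-mean score.
* Score categories are contiguous half-open bins
  $[25.5, 26)$, $[26, 26.5)$, $[26.5, \infty)$ against a $<25.5$ reference.
  Published category labels with gaps ("25.5–25.9, 26.0–26.5") are read as
  these contiguous bins; the cutpoints are configurable, and the reference
  cutpoint is exposed because published footnotes are ambiguous between
  25 and 25.5.
* Instruments with $|\beta_{XG}|/S_{XG} < 2$ are flagged weak but retained.

## Calibration of the diagnostic tests

Two design notes on the simulation-based checks shipped with the package:

* **IVW null calibration uses first-order weights.** Conditional on the
  exposure estimates, the first-order IVW z-statistic is *exactly* standard
  normal under the null, at any instrument strength. Delta-method weights
  depend on the outcome estimates, which makes the combined z-statistic
  conservative when instruments are individually weak (z SD around 0.8 in
  our desk-scale conditions, 0.97–1.00 for first-order). The delta-method
  SE remains the package default for estimation, matching the stated
  formula; the calibration check uses the mode that is exactly calibrated.
* **Egger recovery needs a strong exposure study.** When instruments are
  oriented on noisy estimated signs, instruments whose estimated effect is
  near zero flip sign at random, dragging
  $E[\beta_{YG} \mid \beta_{XG} \to 0]$ — and hence the intercept — toward
  zero. With the significance-floor effect distribution and an exposure
  study of 60,000+ (the real discovery GWAS had ~339,000), orientation is
  essentially error-free and an injected intercept of 0.01 is recovered to
  well within $\pm 0.003$.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run the generator at sizes chosen
as a compromise the package's own CI budget can carry: cohorts of 10,000
(5,000 cases) over 50 seeds for one-sample coverage; exposure studies of
20,000 (null calibration, 200 seeds) and 60,000 (Egger recovery, 200
seeds) with outcome studies of 4,000 cases / 6,000 controls; 50,000
individuals for the realized-R$^2$ check. Coverage and calibration
properties are sample-size-invariant, so these scaled-down designs test
the same properties the full consortium sizes would.

## Known limitations

* Calibration uncertainty (the estimated $\hat\beta_1$) is not propagated
  into one-sample confidence intervals; with control sets in the tens of
  thousands and a score $R^2$ near 1%, this inflates effective CI
  non-coverage by roughly one percentage point.
* Fixed-effects combination only; no random-effects, weighted-median or
  mode-based estimators, and no multivariable MR.
* No LD-aware modeling, no proxy-instrument lookup, no genome-build
  liftover, and no imputation-quality filtering — instrument panels are
  consumed as curated data contracts.
* Per-SNP p-values recombined from printed tables are not reproducible to
  printed precision (they depend on unrounded inputs); only odds ratios
  are treated as a reproduction surface.
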