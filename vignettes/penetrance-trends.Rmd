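---
title: "Modeling polygenic penetrance trends across birth cohorts"
author: "pgstrend maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling polygenic penetrance trends across birth cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgstrend)
```

## The question and the model

A polygenic score (PGS) summarizes a person's genotype as a single weighted
sum of trait-associated allele counts, with weights taken from an external
genome-wide association study (GWAS).  How strongly that score predicts its
phenotype — its *penetrance* — is not a biological constant: it depends on
the environment the cohort grew up in.  Nutritional abundance can let
height- and BMI-associated variants express themselves more fully;
educational expansion can compress genetic differences in attainment.
`pgstrend` estimates whether penetrance drifts linearly across birth
cohorts.

The core model is an ordinary least squares fit of a phenotype $y_i$ on the
standardized score $S_i$, the birth year centered at its sample mean
$c_i = \mathrm{by}_i - \overline{\mathrm{by}}$, and their product:

$$y_i = \alpha + \beta_{\mathrm{pgs}} S_i + \beta_{\mathrm{yr}} c_i +
\beta_{\mathrm{int}}\, S_i c_i + \varepsilon_i .$$

$\beta_{\mathrm{int}}$ — the change in the score's effect per year of birth
— is the quantity of interest.  It is invariant to the centering constant;
centering merely makes $\beta_{\mathrm{pgs}}$ the effect at the average
birth year.  Binary outcomes are fitted with the same linear-probability
form so coefficients stay comparable across phenotypes; a logistic fit
would change the scale of every comparison without changing the question.

Three complications surround this regression, and one module addresses
each.

### Score construction (`match_variants`, `compute_scores`)

Weights are joined to panel variants by id.  Records whose allele pair is
self-complementary (A/T or C/G) are removed: such "strand-ambiguous" SNPs
can silently refer to either strand, so the effect allele cannot be trusted
from labels alone.  Records whose effect allele matches the panel REF
rather than ALT are kept with the complement dosage $2 - x$.  No p-value
threshold is applied anywhere: weakly associated SNPs carry small weights
and down-weight themselves.  The raw score is the *sum*
$\sum_j d_{ij} w_j$, not the average; after standardization to mean 0 /
SD 1 — which every downstream stage consumes — the two are affinely
identical, and the sum avoids ambiguity when per-sample missingness varies.
Missing dosages are imputed with the variant's mean observed dosage
($2\hat p$), the common behavior of scoring tools, so every sample gets a
score.

### Population structure (`compute_pcs`, `residualize`)

If allele frequencies and phenotype means both drift across subpopulations,
a score-phenotype association can be pure stratification.  Genotype
principal components are computed on a designated reference subgroup
(dosages centered by $2\hat p$ and scaled by $\sqrt{2\hat p(1-\hat p)}$,
the Hardy-Weinberg variance scaling; monomorphic variants dropped), all
samples are projected onto the reference loadings, and the standardized
score is replaced by its re-standardized OLS residual on the top $k = 10$
components.  Each component's sign is fixed so its largest-magnitude
loading is positive — SVD signs are otherwise arbitrary and would break
reproducibility.  Residualization is idempotent and exactly orthogonal to
the retained components; with $k = 0$ it is the identity.

### Household clustering and measurement error (`cluster_robust_vcov`, `simex_correct`)

Survey cohorts contain spouses who share households, diets and residual
shocks, so observations are not independent.  The sandwich covariance
$(X'X)^{-1}\left(\sum_g X_g' u_g u_g' X_g\right)(X'X)^{-1}$ clustered by
household, with the CR1 factor $\frac{G}{G-1}\frac{n-1}{n-k}$, makes the
reported standard errors robust to that; with singleton households it
collapses to the HC1 heteroskedasticity-robust estimator, and p-values use
$t_{G-1}$.

A score built from noisy published weights measures the true genetic
propensity with classical error, attenuating every coefficient toward
zero.  SIMEX makes the problem deliberately worse — adding
$N(0, \lambda\sigma^2_u)$ noise for $\lambda \in \{0.5, 1, 1.5, 2\}$,
refitting $B = 100$ times per $\lambda$, and averaging — then extrapolates
the coefficient trend with a quadratic in $\lambda$ back to $\lambda = -1$,
the zero-error point.  The quadratic extrapolant and that grid are the
standard defaults of the SIMEX literature.  The error variance
$\sigma^2_u$ must be supplied by the caller; for a score with reliability
$r$ on the standardized-truth scale the pipeline uses
$\sigma^2_u = (1-r)/r$, with $r = 0.8$ as the fixture default — a typical
published reliability for scores built from moderately powered GWAS.

### Variance stability (`variance_by_cohort`)

A penetrance trend could also be produced by the score's *variance*
changing across cohorts (differential fertility, assortative mating) rather
than by gene-environment interaction.  The check cuts birth years into
equal-frequency bins, reports per-bin variances, and tests homogeneity with
the Brown-Forsythe statistic — one-way ANOVA on absolute deviations from
bin medians, chosen over Bartlett because polygenic scores need not be
normal and Bartlett is notoriously sensitive to that.  Because an omnibus
homogeneity test is weak against a monotone drift, the OLS slope of squared
deviations on centered birth year is reported alongside it.

### The cohort figure (`binned_means`, `fitted_lines`)

The standard visual is two fitted lines (predictions at score $\pm 1$ SD;
their vertical gap is exactly $2(\beta_{\mathrm{pgs}} +
\beta_{\mathrm{int}} c)$, so parallel lines mean no trend) over two point
clouds: the sample split at score 0, each half cut into 20 birth-year rank
bins of near-equal size, plotting each bin's mean birth year against its
mean response.  Exact score zeros join the below group — a measure-zero
event for continuous scores.  Within a group, birth-year ties are broken
by response value, not input index, so the summary is invariant to row
order; any bin-size remainder goes to the earliest bins.

## What the synthetic cohort emulates

Real applications of this model use restricted survey genotypes, so the
package ships a generator whose defaults state a mid-20th-century US survey
world:

* **Genotypes.** Biallelic SNPs, ancestral frequencies uniform on
  (0.05, 0.5), Hardy-Weinberg dosages, *no linkage disequilibrium*.  An
  optional two-subpopulation mode draws subgroup frequencies from a
  Balding-Nichols model around the ancestral frequency (`fst` controls the
  divergence; `fst = 0` collapses it).
* **Published weights.** True effects $N(0, \tau^2)$ plus independent
  estimation noise; 10% of records are deliberately emitted with
  strand-ambiguous allele pairs purely to exercise the filter.
* **Cohort.** Birth years uniform integers on 1919-1955 (the emulated
  surveys report only the range, so uniform is the maximum-entropy choice);
  half the sample paired into two-person households, with an
  assortative-mating knob that pairs people by a noisy copy of their score
  (the noise SD is chosen so the induced partner correlation approximately
  equals the requested value — rank-matching cannot hit it exactly, which
  the tests respect).
* **Phenotypes.** One latent law for every channel,
  $y = \alpha + \gamma c + (\beta_0 + \beta_1 c)S + h + e$, with a shared
  household residual $h$ and independent person noise per channel.
  Channels are then dressed to natural scales: education rounded to years
  around 13; BMI and height affine in the latent (defaults 27 ± 3 kg/m²
  and 1.70 ± 0.10 m) with wave-to-wave measurement noise; heart disease by
  thresholding its latent at the normal quantile of the latent's
  *theoretical* SD so the marginal prevalence is 40% by construction, not
  estimation; CESD as the exponentiated latent, giving the right skew that
  motivates the $\log(\bar x + 1)$ transform.
* **Mortality selection.** Retention probability
  $\mathrm{logit}^{-1}(4 - \text{slope} \cdot x \cdot \text{age in
  decades})$ with $x$ the centered phenotype and age taken at a fixed 2012
  observation wave.  The offset 4 sets ~98% baseline retention; a slope of
  exactly 0 returns the table unchanged.  This is a *generic* survivor-bias
  mechanism — the attrition process of any real survey is unknown, so no
  attempt is made to match one.

What a green test therefore establishes: the estimator recovers a linear
penetrance trend it was built to detect, under independent SNPs, a
correctly linear generating law, and Gaussian noise.  What it does not
establish: behavior under linkage disequilibrium, non-linear cohort
effects, case ascertainment, or real GWAS weight correlation structure.

## Numerical choices and degenerate inputs

* Standardization refuses zero-variance inputs with an explicit error
  (all-zero weights, a score lying in the span of the PCs).  The
  residualization variant uses an absolute SD threshold of `1e-8` — the
  input is standardized, so anything smaller means collinearity, not
  signal.
* `fit_interaction` requires 10 complete observations, rejects
  rank-deficient designs, and drops incomplete rows rather than erroring.
* Equal-frequency binning uses `ceiling(rank * bins / n)` with first-come
  tie-breaking; the variance check refuses bins under 10 observations and
  constant scores.
* The natural logarithm is used for the CESD transform; the base is
  immaterial to standardized inference but fixed for reproducibility.
* All generator randomness flows from one integer seed (panel at `seed`,
  phenotypes at `seed + 1`, mortality at `seed + 2`), restoring the
  caller's RNG state afterwards; SIMEX takes its own seed and is
  deterministic given it.
* Config files are JSON rather than YAML — the deployment environment
  carries no R YAML parser, and JSON loses nothing for a flat key-value
  config.

## Open design points, decided

* *Sum vs average in the score*: sum (see above); immaterial after
  standardization.
* *"Reference allele"* in the score definition is read as the
  effect-allele dosage — the only reading under which the weight's sign
  means anything.
* *Matching key*: variant id only; no positional liftover is attempted
  because the formats carry no assembly information.
* *Education capping*: none; the emulated surveys cap years of education
  at 17, but the generator's rounded-Gaussian years are left uncapped since
  no analysis step depends on the tail.
* *PC set*: components are computed on the scoring SNP panel itself; if a
  genome-wide panel is available it can be passed as its own
  `genotype_panel`.
* *Recovery experiments* publish noiseless, unambiguous weights and set the
  BMI channel's scale to 1 so the fitted interaction is directly comparable
  to the configured $\beta_1$; attenuation from deliberately noisy weights
  is what the SIMEX tests are for, and the two worlds are kept separate on
  purpose.
* *Statistical tolerances* were fixed before first execution: means of
  replicated estimates are held to 2 Monte-Carlo SEs; rejection rates to
  99% binomial intervals; single-frequency convergence to 3 SE with a
  Bonferroni-widened band when 30 frequencies are checked jointly.

## Known limitations

* Independent SNPs only; with real LD the effective number of independent
  weights is smaller and score reliability lower than the generator implies.
* The linear-probability fit for the binary phenotype can predict outside
  [0, 1] at extreme scores; a logistic alternative is a config away but
  breaks cross-phenotype coefficient comparability.
* SIMEX assumes classical, additive, normal measurement error with known
  variance; a misspecified reliability shifts the corrected estimate
  accordingly.
* The assortative-mating knob targets the couple correlation only
  approximately, and the mortality model is generic rather than calibrated
  to any real attrition process.
* Quadratic SIMEX extrapolation is a convention, not a theorem; with
  strongly nonlinear attenuation profiles the corrected point retains bias.
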