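# pgstrend

Does a polygenic score predict its phenotype equally well for people born
in 1920 and people born in 1955?  `pgstrend` is an R package for asking
that question properly.  It is aimed at social-science genomics and
genetic-epidemiology analysts who have (i) GWAS summary-statistic weight
files and (ii) a genotyped survey cohort spanning several decades of birth
years, and who want to estimate how *penetrance* — the association between
an additive polygenic score (PGS) and its phenotype — changes across birth
cohorts, with the standard methodological guards in place.

## The model

For person *i* with standardized score `S`, birth year centered at the
sample mean `c`, and phenotype `y`:

```
y_i = α + β_pgs · S_i + β_yr · c_i + β_int · S_i · c_i + ε_i
```

`β_int`, the change in the score's effect per year of birth, is the
estimand.  Around this regression the package provides:

* **Score construction** from tab-delimited GWAS weights and a VCF panel:
  allele matching by variant id, removal of strand-ambiguous (A/T, C/G)
  records, complement-dosage handling of flipped records, mean-dosage
  imputation of missing genotypes, no p-value threshold, and
  standardization to mean 0 / SD 1.
* **Population-structure adjustment**: genotype PCA on a reference
  subgroup (PLINK-style `2p(1−p)` scaling), projection of all samples,
  and re-standardized residualization of the score on the top 10
  components.
* **Inference**: classical OLS covariance plus household-clustered
  Huber-White (CR1) covariance for spousal non-independence.
* **Measurement-error correction**: SIMEX — add noise at multipliers
  λ ∈ {0.5, 1, 1.5, 2}, refit, extrapolate a quadratic back to λ = −1.
* **Variance stability**: per-cohort score variances with a
  Brown-Forsythe homogeneity test and a variance-trend slope, to separate
  gene-by-environment trends from drifting genetic variance.
* **Cohort figure summaries**: fitted lines at score ±1 SD and 20
  equal-size birth-year bins of mean response per score-sign group.
* **A synthetic cohort generator** (genotypes under Hardy-Weinberg with
  optional two-subpopulation Balding-Nichols structure, noisy published
  weights, spousal households with an assortative-mating knob, wave-long
  phenotypes with a known penetrance trend, optional mortality selection)
  so the whole pipeline is testable without restricted data.

## Worked example

```r
library(pgstrend)

cfg <- sim_config(n_samples = 2000, n_variants = 100, seed = 7)
sim <- simulate_panel(cfg)                                # genotypes + weights
waves <- simulate_phenotypes(sim$panel, sim$truth, cfg)   # wave-long table
fixture <- write_fixture(sim, waves, tempfile("cohort_")) # VCF / TSV / CSV

report <- run_pipeline(fixture,
                       phenotypes = c("bmi", "height", "educ", "heart", "cesd"),
                       k_pcs = 10, reliability = 0.8, seed = 7)
print(report)
```

```
<pgs_trend_report> 2000 samples, 100 variants, 90 matched
  bmi     b_int = +0.05487 (p = 2.02e-17, cluster p = 8.86e-17)  SIMEX +0.06927  var-stab p = 0.556 
  height  b_int = +0.00149 (p = 6.1e-12, cluster p = 4.05e-12)  SIMEX +0.00187  var-stab p = 0.556 
  educ    b_int = +0.03442 (p = 2.43e-15, cluster p = 2.55e-14)  SIMEX +0.04260  var-stab p = 0.556 
  heart   b_int = +0.00635 (p = 1.68e-10, cluster p = 1.42e-11)  SIMEX +0.00814  var-stab p = 0.556 
  cesd    b_int = +0.00777 (p = 1.36e-11, cluster p = 5.58e-12)  SIMEX +0.00971  var-stab p = 0.556 
```

Reading the output: 90 of 100 published weight records matched the panel
(the simulated 10% strand-ambiguous records were filtered).  The
generator's penetrance slope is `beta1 = 0.02` per year on the latent
scale; each phenotype shows it through its own dressing — e.g. BMI is
scaled by 3 kg/m² per latent unit, so its fitted `b_int ≈ 0.055` sits near
`3 × 0.02` (shrunk slightly by weight noise and wave noise), and the SIMEX
column moves it back up.  `p` and `cluster p` are the classical and
household-clustered p-values for `b_int`; `var-stab p` is the
Brown-Forsythe p-value, here comfortably non-significant — the score's
variance is stable across cohorts, as simulated.

Every stage is also exposed separately (`match_variants`,
`compute_scores`, `compute_pcs`, `residualize`, `derive_phenotypes`,
`fit_interaction`, `cluster_robust_vcov`, `simex_correct`,
`variance_by_cohort`, `binned_means`, `fitted_lines`,
`plot_penetrance`), and a CLI mirrors the pipeline:

```sh
Rscript -e 'pgstrend::pgstrend_cli()' simulate --config cfg.json --out fx --seed 12
Rscript -e 'pgstrend::pgstrend_cli()' score --vcf fx/genotypes.vcf \
    --weights fx/weights.tsv --out scores.csv
Rscript -e 'pgstrend::pgstrend_cli()' trend --scores scores.csv \
    --phenotypes persons.csv --phenotype bmi --out report.json
```

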