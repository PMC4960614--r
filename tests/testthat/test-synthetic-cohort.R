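test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_samples = 0), "positive integer")
  expect_error(sim_config(n_variants = -3), "positive integer")
  expect_error(sim_config(maf_range = c(0.5, 0.1)), "increasing pair")
  expect_error(sim_config(maf_range = c(0, 0.5)), "within")
  expect_error(sim_config(n_subpops = 3), "1 or 2")
  expect_error(sim_config(birth_year_range = c(1950, 1950)), "min < max")
  expect_error(sim_config(noise_sd = -1), ">= 0")
  expect_error(sim_config(spouse_fraction = 1.2), "\\[0, 1\\]")
})

test_that("zero weight noise publishes the true weights", {
  sim <- simulate_panel(sim_config(n_samples = 20, n_variants = 30,
                                   weight_noise_sd = 0, seed = 3))
  expect_identical(unname(sim$truth$true_weights), sim$weights$beta)
})

test_that("dosages follow Hardy-Weinberg at the generating frequency", {
  # single fixed-frequency variant: variance -> 2p(1-p)
  sim <- simulate_panel(sim_config(n_samples = 10000, n_variants = 1,
                                   maf_range = c(0.5 - 1e-9, 0.5), seed = 4))
  expect_equal(var(as.vector(sim$panel$dosages)), 0.5, tolerance = 0.05)

  # empirical frequency converges on the generating frequency: a single
  # designated variant is held to the 3 SE tolerance; across all 30
  # variants jointly the band is Bonferroni-widened to 4.2 SE
  sim2 <- simulate_panel(sim_config(n_samples = 10000, n_variants = 30,
                                    seed = 5))
  p <- sim2$panel$variants$af
  p_hat <- colMeans(sim2$panel$dosages) / 2
  se <- sqrt(p * (1 - p) / (2 * 10000))
  expect_lt(abs(p_hat[1] - p[1]), 3 * se[1])
  expect_true(all(abs(p_hat - p) < 4.2 * se))
})

test_that("fst = 0 collapses Balding-Nichols onto the ancestral frequency", {
  sim <- simulate_panel(sim_config(n_samples = 4000, n_variants = 20,
                                   n_subpops = 2, fst = 0, seed = 6))
  p <- sim$panel$variants$af
  for (k in 1:2) {
    sub <- sim$panel$subpop == k
    p_hat <- colMeans(sim$panel$dosages[sub, ]) / 2
    se <- sqrt(p * (1 - p) / (2 * sum(sub)))
    expect_true(all(abs(p_hat - p) < 4 * se))
  }
})

test_that("fst > 0 makes subpopulation frequencies diverge", {
  sim <- simulate_panel(sim_config(n_samples = 2000, n_variants = 100,
                                   n_subpops = 2, fst = 0.2, seed = 7))
  d <- abs(colMeans(sim$panel$dosages[sim$panel$subpop == 1, ]) -
             colMeans(sim$panel$dosages[sim$panel$subpop == 2, ])) / 2
  expect_gt(mean(d), 0.05)
})

test_that("fixed seed reproduces panel, weights and phenotypes exactly", {
  cfg <- sim_config(n_samples = 60, n_variants = 25, seed = 8,
                    spouse_score_corr = 0.5, household_noise_sd = 0.3)
  a <- simulate_panel(cfg); b <- simulate_panel(cfg)
  expect_identical(a, b)
  wa <- simulate_phenotypes(a$panel, a$truth, cfg)
  wb <- simulate_phenotypes(b$panel, b$truth, cfg)
  expect_identical(wa, wb)
})

test_that("published records flag the configured ambiguous fraction", {
  sim <- simulate_panel(sim_config(n_samples = 10, n_variants = 50,
                                   ambiguous_fraction = 0.2, seed = 9))
  amb <- is_ambiguous_pair(sim$weights$effect_allele,
                           sim$weights$other_allele)
  expect_equal(sum(amb), 10)
  sim0 <- simulate_panel(sim_config(n_samples = 10, n_variants = 50,
                                    ambiguous_fraction = 0, seed = 9))
  expect_false(any(is_ambiguous_pair(sim0$weights$effect_allele,
                                     sim0$weights$other_allele)))
})

test_that("true scores equal dosages times true weights", {
  sim <- simulate_panel(sim_config(n_samples = 40, n_variants = 15,
                                   seed = 10))
  expect_equal(unname(sim$truth$true_scores),
               unname(drop(sim$panel$dosages %*% sim$truth$true_weights)))
})

test_that("noiseless unit-penetrance phenotype equals the standardized score", {
  cfg <- sim_config(n_samples = 100, n_variants = 20, seed = 11,
                    noise_sd = 0, gamma = 0, beta1 = 0, beta0 = 1, alpha = 0,
                    wave_noise_sd = 0, household_noise_sd = 0,
                    bmi_location = 0, bmi_scale = 1, n_waves = 2)
  sim <- simulate_panel(cfg)
  waves <- simulate_phenotypes(sim$panel, sim$truth, cfg)
  s <- attr(waves, "s_std")
  expect_equal(mean(s), 0, tolerance = 1e-12)
  expect_equal(sd(s), 1, tolerance = 1e-12)
  expect_equal(waves$bmi, unname(s[waves$person_id]), tolerance = 1e-12)
})

test_that("null penetrance trend yields a null interaction estimate", {
  cfg <- sim_config(n_samples = 2000, n_variants = 40, seed = 12,
                    beta1 = 0, weight_noise_sd = 0)
  sim <- simulate_panel(cfg)
  waves <- simulate_phenotypes(sim$panel, sim$truth, cfg)
  per <- derive_phenotypes(waves)
  s <- attr(waves, "s_std")[per$person_id]
  fit <- fit_interaction(per$bmi_mean, s, per$birth_year)
  expect_lt(abs(coef(fit)[["score:byear_c"]]),
            3 * fit$se_classical[["score:byear_c"]])
})

test_that("random spousal pairing leaves couple scores uncorrelated, assortative pairing does not", {
  couple_cor <- function(rho, seed) {
    cfg <- sim_config(n_samples = 2000, n_variants = 30, seed = seed,
                      spouse_fraction = 1, spouse_score_corr = rho)
    sim <- simulate_panel(cfg)
    waves <- simulate_phenotypes(sim$panel, sim$truth, cfg)
    one <- waves[waves$wave == 1, ]
    s <- attr(waves, "s_std")[one$person_id]
    pairs <- split(s, one$household_id)
    pairs <- do.call(rbind, pairs[lengths(pairs) == 2])
    cor(pairs[, 1], pairs[, 2])
  }
  expect_lt(abs(couple_cor(0, 13)), 0.08)
  expect_gt(couple_cor(0.8, 14), 0.5)
})

test_that("mortality selection: null slope is the identity", {
  sc <- small_cohort(seed = 15)
  expect_identical(apply_mortality_selection(sc$waves, sc$cfg), sc$waves)
})

test_that("mortality selection thins older cohorts and lowers their phenotype mean", {
  # gamma = 0 keeps the phenotype distribution identical across cohorts so
  # the age gradient of the thinning is isolated from the secular trend
  cfg <- sim_config(n_samples = 6000, n_variants = 60, seed = 5, beta1 = 0,
                    beta0 = 1, gamma = 0, mortality_slope = 1.5,
                    weight_noise_sd = 0)
  sim <- simulate_panel(cfg)
  waves <- simulate_phenotypes(sim$panel, sim$truth, cfg)
  surv <- apply_mortality_selection(waves, cfg)
  full <- derive_phenotypes(waves)
  kept <- derive_phenotypes(surv)
  expect_lt(nrow(kept), nrow(full))

  old <- full$birth_year <= 1930
  old_kept <- kept$birth_year <= 1930
  # survivors' phenotype mean strictly below the full-cohort mean among old
  expect_lt(mean(kept$bmi_mean[old_kept]), mean(full$bmi_mean[old]))
  # older cohorts thinned harder than younger ones
  retained <- table(full$person_id %in% kept$person_id, old)
  frac_old <- mean(full$person_id[old] %in% kept$person_id)
  frac_young <- mean(full$person_id[!old] %in% kept$person_id)
  expect_lt(frac_old, frac_young)
})

test_that("phenotype-dependent selection can fake a score-variance trend under a null beta1", {
  # documented simulation experiment: with beta1 = 0 but strong selection on
  # a score-linked phenotype, the naive variance-by-cohort supplement shows
  # a trend, so a flat variance profile is informative about selection too.
  cfg <- sim_config(n_samples = 6000, n_variants = 60, seed = 5, beta1 = 0,
                    beta0 = 1, mortality_slope = 1.5, weight_noise_sd = 0)
  sim <- simulate_panel(cfg)
  waves <- simulate_phenotypes(sim$panel, sim$truth, cfg)
  surv <- apply_mortality_selection(waves, cfg)
  per <- derive_phenotypes(surv)
  s <- attr(surv, "s_std")[per$person_id]
  vr <- variance_by_cohort(s, per$birth_year, 6)
  expect_lt(vr$slope_pvalue, 0.05)
})

test_that("heart prevalence lands near its constructed target", {
  sc <- small_cohort(seed = 16, n = 4000)
  per <- derive_phenotypes(sc$waves)
  expect_lt(abs(mean(per$heart_ever) - 0.40), 0.03)
})
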