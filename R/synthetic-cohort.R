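# Synthetic cohort generator: genotypes, noisy published weights, wave-long
# phenotypes with a known penetrance trend, and optional mortality selection.

# Allele pairs; strand-ambiguous pairs are the self-complementary ones.
.ambiguous_pairs <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
.unambiguous_pairs <- list(
  c("A", "C"), c("C", "A"), c("A", "G"), c("G", "A"),
  c("C", "T"), c("T", "C"), c("G", "T"), c("T", "G")
)

#' Is an allele pair strand-ambiguous?
#'
#' A/T and C/G pairs are their own reverse complement, so the effect allele
#' cannot be resolved from allele labels alone.
#'
#' @param a1,a2 character vectors of single bases.
#' @return logical vector.
#' @export
is_ambiguous_pair <- function(a1, a2) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  unname(comp[toupper(a1)] == toupper(a2))
}

#' Simulate a genotype panel with published GWAS weights
#'
#' Draws ancestral allele frequencies uniformly on `maf_range`; with two
#' subpopulations, per-subpopulation frequencies follow a Balding-Nichols
#' model, `p_k ~ Beta(p (1 - F) / F, (1 - p)(1 - F) / F)`, collapsing to the
#' ancestral `p` when `fst = 0`.  Dosages are Binomial(2, p) per sample
#' (Hardy-Weinberg, no linkage disequilibrium).  True per-variant effects are
#' Normal(0, `weight_scale`^2); published weights add independent
#' Normal(0, `weight_noise_sd`^2) estimation error.  Published records carry
#' the panel ALT as effect allele and REF as other allele, except for a
#' configurable fraction of variants deliberately given strand-ambiguous
#' allele pairs (A/T or C/G) so the downstream filter has something to
#' remove.
#'
#' @param config a [sim_config()].
#' @return a list with elements `panel` ([genotype_panel()]), `weights`
#'   ([gwas_weights()]) and `truth` (list with `true_weights`, `true_scores`
#'   — the dosage matrix times the true weights, before any standardization —
#'   and the generating `alpha`, `beta0`, `beta1`, `gamma`).
#' @examples
#' sim <- simulate_panel(sim_config(n_samples = 50, n_variants = 20, seed = 7))
#' dim(sim$panel)
#' @export
simulate_panel <- function(config) {
  config <- validate_sim_config(config)
  n <- config$n_samples
  m <- config$n_variants
  with_seed(config$seed, {
    p_anc <- runif(m, config$maf_range[1], config$maf_range[2])

    if (config$n_subpops == 2L) {
      subpop <- rep_len(c(1L, 2L), n)[sample.int(n)]
      f <- config$fst
      if (f > 0) {
        shape1 <- p_anc * (1 - f) / f
        shape2 <- (1 - p_anc) * (1 - f) / f
        p_sub <- cbind(rbeta(m, shape1, shape2), rbeta(m, shape1, shape2))
        # keep frequencies polymorphic even under strong drift
        p_sub <- pmin(pmax(p_sub, 1e-4), 1 - 1e-4)
      } else {
        p_sub <- cbind(p_anc, p_anc)
      }
      freq <- p_sub[cbind(rep(seq_len(m), each = n),
                          rep(subpop, times = m))]
      dos <- matrix(rbinom(n * m, 2L, freq), nrow = n, ncol = m)
    } else {
      subpop <- rep(1L, n)
      dos <- matrix(rbinom(n * m, 2L, rep(p_anc, each = n)),
                    nrow = n, ncol = m)
    }

    n_amb <- round(config$ambiguous_fraction * m)
    amb_idx <- if (n_amb > 0) sample.int(m, n_amb) else integer(0)
    pair_idx <- sample.int(length(.unambiguous_pairs), m, replace = TRUE)
    pairs <- do.call(rbind, .unambiguous_pairs)[pair_idx, , drop = FALSE]
    if (n_amb > 0) {
      amb_pair_idx <- sample.int(length(.ambiguous_pairs), n_amb,
                                 replace = TRUE)
      pairs[amb_idx, ] <- do.call(rbind, .ambiguous_pairs)[amb_pair_idx, ,
                                                           drop = FALSE]
    }

    variants <- data.frame(
      id = sprintf("rs%06d", seq_len(m)),
      ref = pairs[, 1], alt = pairs[, 2],
      pos = seq_len(m) * 1000L,
      af = p_anc,
      stringsAsFactors = FALSE
    )
    sample_ids <- sprintf("S%05d", seq_len(n))
    panel <- genotype_panel(dos, variants, sample_ids, subpop = subpop)

    true_w <- rnorm(m, 0, config$weight_scale)
    pub_w <- true_w + if (config$weight_noise_sd > 0) {
      rnorm(m, 0, config$weight_noise_sd)
    } else 0
    se <- if (config$weight_noise_sd > 0) {
      rep(config$weight_noise_sd, m)
    } else rep(NA_real_, m)
    pval <- ifelse(is.na(se), NA_real_, 2 * pnorm(-abs(pub_w) / se))
    weights <- gwas_weights(variants$id,
                            effect_allele = variants$alt,
                            other_allele = variants$ref,
                            beta = pub_w, se = se, pval = pval)

    truth <- list(true_weights = setNames(true_w, variants$id),
                  true_scores = setNames(drop(dos %*% true_w), sample_ids),
                  alpha = config$alpha, beta0 = config$beta0,
                  beta1 = config$beta1, gamma = config$gamma)
    list(panel = panel, weights = weights, truth = truth)
  })
}

# Pair 2*n_couples individuals into households.  With target correlation
# rho > 0, couples are matched on a noisy copy of the standardized score
# (rank-adjacent pairing); the noise SD is chosen so the induced partner
# score correlation is approximately rho.  rho <= 0 pairs at random.
assign_households <- function(s_std, spouse_fraction, rho) {
  n <- length(s_std)
  n_couples <- floor(spouse_fraction * n / 2)
  household <- seq_len(n)  # provisional: everyone alone
  if (n_couples > 0) {
    chosen <- sample.int(n, 2L * n_couples)
    if (rho > 0) {
      k <- sqrt(max(0, 1 / sqrt(rho) - 1))
      noisy <- s_std[chosen] + rnorm(length(chosen), 0, k)
      chosen <- chosen[order(noisy)]
    } else {
      chosen <- chosen[sample.int(length(chosen))]
    }
    couple_of <- rep(seq_len(n_couples), each = 2)
    household[chosen] <- n + couple_of  # ids disjoint from singleton ids
  }
  # relabel compactly and stably
  as.integer(factor(household, levels = unique(household)))
}

#' Simulate wave-long phenotypes with a birth-cohort penetrance trend
#'
#' Every phenotype channel shares one generating law.  With centered birth
#' year `c` and standardized true score `S`, the person-level latent trait is
#' `y = alpha + gamma * c + (beta0 + beta1 * c) * S + h + e`, with `h` a
#' shared household residual and `e` an independent person residual; each
#' channel (education, BMI, height, heart, CESD) draws its own `e`.  Channels
#' are then dressed to their natural scales: education is rounded years,
#' BMI and height are affine transforms of the latent with per-wave
#' measurement noise, heart disease thresholds the latent so that the
#' marginal prevalence matches `heart_prevalence` by construction (normal
#' quantile of the latent's theoretical SD), and CESD exponentiates the
#' latent to give the right-skewed symptom score.
#'
#' @param panel a [genotype_panel()] from [simulate_panel()].
#' @param truth the matching ground-truth list.
#' @param config the same [sim_config()].
#' @return a wave-long data.frame with columns `person_id`, `household_id`,
#'   `birth_year`, `wave`, `educ`, `bmi`, `height`, `heart`, `cesd`, plus
#'   attribute `"s_std"` (the standardized true score used in generation).
#' @export
simulate_phenotypes <- function(panel, truth, config) {
  config <- validate_sim_config(config)
  n <- length(panel$sample_ids)
  if (length(truth$true_scores) != n) {
    stop("ground truth inconsistent with panel", call. = FALSE)
  }
  with_seed(config$seed + 1L, {
    yr_rng <- config$birth_year_range
    birth_year <- sample(seq(yr_rng[1], yr_rng[2]), n, replace = TRUE)
    cc <- birth_year - mean(yr_rng)
    s_std <- standardize(truth$true_scores, "true score")

    household <- assign_households(s_std, config$spouse_fraction,
                                   config$spouse_score_corr)
    house_eff <- if (config$household_noise_sd > 0) {
      rnorm(max(household), 0, config$household_noise_sd)[household]
    } else rep(0, n)

    gen <- config$alpha + config$gamma * cc +
      (config$beta0 + config$beta1 * cc) * s_std + house_eff
    latent <- function() gen + rnorm(n, 0, config$noise_sd)

    y_educ <- latent(); y_bmi <- latent(); y_height <- latent()
    y_heart <- latent(); y_cesd <- latent()

    # theoretical latent SD: c is uniform-integer and independent of S
    v_c <- (diff(yr_rng) + 1)^2 / 12 - 1 / 12
    sd_lat <- sqrt(config$gamma^2 * v_c + config$beta0^2 +
                     config$beta1^2 * v_c + config$noise_sd^2 +
                     config$household_noise_sd^2)
    thr <- config$alpha + qnorm(1 - config$heart_prevalence) * sd_lat
    heart <- as.integer(y_heart > thr)

    educ <- pmax(0, round(13 + 2 * y_educ))

    wn <- function() {
      if (config$wave_noise_sd > 0) {
        rnorm(n * config$n_waves, 0, config$wave_noise_sd)
      } else 0
    }
    idx <- rep(seq_len(n), times = config$n_waves)
    out <- data.frame(
      person_id = panel$sample_ids[idx],
      household_id = sprintf("H%05d", household[idx]),
      birth_year = birth_year[idx],
      wave = rep(seq_len(config$n_waves), each = n),
      educ = educ[idx],
      bmi = config$bmi_location + config$bmi_scale * (y_bmi[idx] + wn()),
      height = config$height_location +
        config$height_scale * (y_height[idx] + wn()),
      heart = heart[idx],
      cesd = exp(y_cesd[idx] + wn()),
      stringsAsFactors = FALSE
    )
    out <- out[order(out$person_id, out$wave), ]
    rownames(out) <- NULL
    attr(out, "s_std") <- setNames(s_std, panel$sample_ids)
    out
  })
}

#' Thin a cohort by phenotype-dependent mortality
#'
#' Each person is retained with probability
#' `plogis(keep_intercept - mortality_slope * x * age_decades)`, where `x` is
#' the person's mean of `phenotype` centered at the sample mean and
#' `age_decades = (observation_year - birth_year) / 10`.  The log-odds of
#' exclusion thus grow by `mortality_slope` per unit phenotype per decade of
#' age, so older cohorts are thinned harder and against the high-phenotype
#' side; `keep_intercept` sets the baseline retention.  `mortality_slope =
#' 0` disables selection entirely and returns the table unchanged — a
#' generic survivor-bias mechanism with a clean off switch.
#'
#' @param wave_table wave-long table from [simulate_phenotypes()].
#' @param config a [sim_config()] supplying `mortality_slope` and
#'   `observation_year`.
#' @param seed RNG seed for the retention draws (default derived from the
#'   config seed).
#' @param phenotype which column drives selection (default `"bmi"`).
#' @param keep_intercept baseline retention log-odds (default 4, i.e. 98%
#'   retention for an average person).
#' @return the surviving subset of `wave_table` (all waves of each retained
#'   person), attributes preserved for survivors.
#' @export
apply_mortality_selection <- function(wave_table, config,
                                      seed = config$seed + 2L,
                                      phenotype = "bmi",
                                      keep_intercept = 4) {
  config <- validate_sim_config(config)
  if (config$mortality_slope == 0) {
    return(wave_table)
  }
  if (!phenotype %in% names(wave_table)) {
    stop(sprintf("phenotype column '%s' not found", phenotype), call. = FALSE)
  }
  per <- aggregate(wave_table[[phenotype]],
                   by = list(person_id = wave_table$person_id),
                   FUN = mean, na.rm = TRUE)
  names(per)[2] <- "phen"
  yr <- wave_table$birth_year[!duplicated(wave_table$person_id)]
  names(yr) <- wave_table$person_id[!duplicated(wave_table$person_id)]
  per$age_dec <- (config$observation_year - yr[per$person_id]) / 10
  per$x <- per$phen - mean(per$phen)
  with_seed(seed, {
    p_keep <- plogis(keep_intercept -
                       config$mortality_slope * per$x * per$age_dec)
    keep_ids <- per$person_id[runif(nrow(per)) < p_keep]
    out <- wave_table[wave_table$person_id %in% keep_ids, ]
    rownames(out) <- NULL
    s <- attr(wave_table, "s_std")
    if (!is.null(s)) attr(out, "s_std") <- s[names(s) %in% keep_ids]
    out
  })
}
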