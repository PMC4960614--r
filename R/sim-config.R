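#' Configuration for the synthetic cohort generator
#'
#' Collects every knob of the simulated world in one validated object.  The
#' defaults describe a mid-20th-century US survey cohort: birth years
#' 1919-1955, roughly half the sample living in two-person (spousal)
#' households, a modest polygenic effect that strengthens linearly with birth
#' year, and phenotypes observed over several interview waves.
#'
#' @param n_samples number of individuals.
#' @param n_variants number of biallelic SNPs.
#' @param maf_range length-2 numeric in (0, 1); ancestral allele frequencies
#'   are drawn uniformly on this interval.
#' @param n_subpops 1 (panmictic) or 2 (two subpopulations whose frequencies
#'   diverge around the ancestral frequency under a Balding-Nichols model).
#' @param fst Balding-Nichols divergence parameter, >= 0; ignored when
#'   `n_subpops = 1`, and `fst = 0` collapses both subpopulations onto the
#'   ancestral frequency.
#' @param weight_scale SD of the per-variant true effect sizes (tau).
#' @param weight_noise_sd SD of the estimation error added to true effects to
#'   produce the "published" GWAS weights; 0 publishes the truth.
#' @param ambiguous_fraction fraction of weight records emitted with a
#'   strand-ambiguous allele pair (A/T or C/G) to exercise the score filter.
#' @param birth_year_range inclusive integer range; birth years are uniform
#'   integers on it.
#' @param alpha phenotype latent-trait intercept.
#' @param beta0 baseline penetrance: phenotype units per SD of true score at
#'   the central birth year.
#' @param beta1 penetrance slope per year of birth — the ground-truth
#'   interaction coefficient the trend model should recover.
#' @param gamma secular (main) effect of birth year on the phenotype.
#' @param noise_sd SD of the person-level residual on each latent trait.
#' @param wave_noise_sd SD of wave-to-wave measurement noise on repeated
#'   phenotype reports.
#' @param household_noise_sd SD of a shared household-level residual
#'   component (induces within-couple error correlation for cluster-robust
#'   testing).
#' @param spouse_fraction fraction of the sample paired into 2-person
#'   households; the rest live alone.
#' @param spouse_score_corr target correlation of true scores within couples
#'   (assortative-mating knob); 0 pairs at random.
#' @param heart_prevalence marginal prevalence targeted by the liability
#'   threshold of the binary phenotype.
#' @param mortality_slope log-odds of exclusion per unit (centered)
#'   phenotype per decade of age at observation; 0 disables selection.
#' @param observation_year calendar year of the observation wave used to
#'   compute ages for mortality selection.
#' @param n_waves number of interview waves.
#' @param bmi_location,bmi_scale affine placement of the continuous
#'   BMI-analogue channel (kg/m^2): `bmi = location + scale * latent`.
#' @param height_location,height_scale affine placement of the continuous
#'   height-analogue channel (meters).
#' @param seed integer RNG seed; fixed seed gives byte-identical output.
#'
#' @return an object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_samples = 200, n_variants = 50, seed = 1)
#' cfg$birth_year_range
#' @export
sim_config <- function(n_samples = 5000,
                       n_variants = 200,
                       maf_range = c(0.05, 0.5),
                       n_subpops = 1,
                       fst = 0,
                       weight_scale = 0.1,
                       weight_noise_sd = 0.05,
                       ambiguous_fraction = 0.10,
                       birth_year_range = c(1919L, 1955L),
                       alpha = 0,
                       beta0 = 0.3,
                       beta1 = 0.02,
                       gamma = 0.01,
                       noise_sd = 1,
                       wave_noise_sd = 0.1,
                       household_noise_sd = 0,
                       spouse_fraction = 0.5,
                       spouse_score_corr = 0,
                       heart_prevalence = 0.40,
                       mortality_slope = 0,
                       observation_year = 2012L,
                       n_waves = 3,
                       bmi_location = 27,
                       bmi_scale = 3,
                       height_location = 1.70,
                       height_scale = 0.10,
                       seed = 1L) {
  cfg <- list(
    n_samples = n_samples, n_variants = n_variants, maf_range = maf_range,
    n_subpops = n_subpops, fst = fst, weight_scale = weight_scale,
    weight_noise_sd = weight_noise_sd, ambiguous_fraction = ambiguous_fraction,
    birth_year_range = as.integer(birth_year_range), alpha = alpha,
    beta0 = beta0, beta1 = beta1, gamma = gamma, noise_sd = noise_sd,
    wave_noise_sd = wave_noise_sd, household_noise_sd = household_noise_sd,
    spouse_fraction = spouse_fraction, spouse_score_corr = spouse_score_corr,
    heart_prevalence = heart_prevalence, mortality_slope = mortality_slope,
    observation_year = as.integer(observation_year), n_waves = n_waves,
    bmi_location = bmi_location, bmi_scale = bmi_scale,
    height_location = height_location, height_scale = height_scale,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot_scalar_count(cfg$n_samples, "n_samples")
  stopifnot_scalar_count(cfg$n_variants, "n_variants")
  stopifnot_scalar_count(cfg$n_waves, "n_waves")
  if (length(cfg$maf_range) != 2 || any(cfg$maf_range <= 0) ||
      any(cfg$maf_range >= 1) || cfg$maf_range[1] > cfg$maf_range[2]) {
    stop("'maf_range' must be an increasing pair within (0, 1)", call. = FALSE)
  }
  if (!cfg$n_subpops %in% c(1L, 2L)) {
    stop("'n_subpops' must be 1 or 2", call. = FALSE)
  }
  if (cfg$birth_year_range[1] >= cfg$birth_year_range[2]) {
    stop("'birth_year_range' must satisfy min < max", call. = FALSE)
  }
  sds <- c(fst = cfg$fst, weight_scale = cfg$weight_scale,
           weight_noise_sd = cfg$weight_noise_sd, noise_sd = cfg$noise_sd,
           wave_noise_sd = cfg$wave_noise_sd,
           household_noise_sd = cfg$household_noise_sd,
           mortality_slope = cfg$mortality_slope)
  bad <- names(sds)[!is.finite(sds) | sds < 0]
  if (length(bad)) {
    stop(sprintf("parameter(s) %s must be >= 0", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  for (p in c("ambiguous_fraction", "spouse_fraction", "heart_prevalence")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) {
      stop(sprintf("'%s' must lie in [0, 1]", p), call. = FALSE)
    }
  }
  if (abs(cfg$spouse_score_corr) > 1) {
    stop("'spouse_score_corr' must lie in [-1, 1]", call. = FALSE)
  }
  cfg
}

#' Read a simulation configuration from a JSON file
#'
#' The file holds a JSON object whose keys are [sim_config()] argument
#' names; unspecified keys keep their defaults.
#'
#' @param path path to a JSON file.
#' @return a validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  do.call(sim_config, raw)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d samples x %d variants, %d subpop(s), fst = %g\n",
              x$n_samples, x$n_variants, x$n_subpops, x$fst))
  cat(sprintf("  birth years %d-%d, %d wave(s)\n",
              x$birth_year_range[1], x$birth_year_range[2], x$n_waves))
  cat(sprintf("  penetrance: beta0 = %g, beta1 = %g /yr, gamma = %g\n",
              x$beta0, x$beta1, x$gamma))
  cat(sprintf("  seed = %d\n", x$seed))
  invisible(x)
}
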