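# End-to-end driver: score -> structure-adjust -> phenotypes -> interaction
# fit -> clustered SEs -> SIMEX -> variance check -> figure summaries.

# user-facing phenotype name -> derived column
.pheno_columns <- c(educ = "educ_years", bmi = "bmi_mean",
                    height = "height_max", heart = "heart_ever",
                    cesd = "cesd_log")

#' Run the full penetrance-trend pipeline on a fixture
#'
#' Reads a genotype VCF, a GWAS weights TSV and a wave-long phenotype CSV;
#' builds and standardizes the polygenic score; residualizes it on the top
#' principal components; derives per-person phenotypes; and, for each
#' requested phenotype, fits the score-by-birth-year interaction with
#' classical and household-clustered covariance, applies SIMEX with the
#' configured score reliability, runs the variance-by-cohort check and the
#' binned-means figure summary.  Re-running with the same inputs and seed
#' reproduces the JSON report byte-identically.
#'
#' @param files named list or vector with elements `vcf`, `weights`,
#'   `phenotypes` (as written by [write_fixture()]).
#' @param phenotypes which phenotypes to analyse (subset of `educ`, `bmi`,
#'   `height`, `heart`, `cesd`).
#' @param k_pcs number of principal components to residualize on (default
#'   10; 0 skips adjustment).
#' @param reference_ids optional character vector of sample ids defining the
#'   PCA reference subgroup (default: all samples).
#' @param reliability assumed score reliability `r` in (0, 1]; SIMEX uses
#'   error variance `(1 - r) / r`.  `reliability = 1` skips SIMEX.
#' @param simex_B,simex_lambda SIMEX replicates and multiplier grid.
#' @param var_bins cohort bins for the variance check.
#' @param fig_bins bins per score-sign group for the figure summary.
#' @param seed integer seed for the SIMEX replicates.
#' @param out optional path; when given the report is written there as JSON.
#' @return an object of class `pgs_trend_report`: `meta`, `match_report`,
#'   and one named block per phenotype with `fit` (coefficients, classical
#'   and clustered SEs and p-values, n), `simex`, `variance`, and
#'   `binned_means`.
#' @export
run_pipeline <- function(files,
                         phenotypes = c("bmi", "height", "educ", "heart",
                                        "cesd"),
                         k_pcs = 10, reference_ids = NULL,
                         reliability = 0.8, simex_B = 100,
                         simex_lambda = c(0.5, 1, 1.5, 2),
                         var_bins = 8, fig_bins = 20, seed = 1L,
                         out = NULL) {
  phenotypes <- match.arg(phenotypes, names(.pheno_columns),
                          several.ok = TRUE)
  if (reliability <= 0 || reliability > 1) {
    stop("reliability must lie in (0, 1]", call. = FALSE)
  }
  files <- as.list(files)

  panel <- read_panel(files$vcf)
  weights <- read_weights(files$weights)
  waves <- read_wave_table(files$phenotypes)

  m <- match_variants(panel, weights)
  scores <- compute_scores(panel, m$matched)
  if (k_pcs > 0) {
    mask <- if (is.null(reference_ids)) NULL else
      panel$sample_ids %in% reference_ids
    k_use <- min(k_pcs, nrow(m$matched) - 1, length(panel$sample_ids) - 2)
    proj <- compute_pcs(panel, mask, k = k_use)
    scores_adj <- residualize(scores, proj)
  } else {
    scores_adj <- residualize(scores, NULL)
  }

  persons <- derive_phenotypes(waves)
  idx <- match(persons$person_id, scores_adj$sample_ids)
  if (anyNA(idx)) {
    persons <- persons[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  s <- scores_adj$std[idx]

  blocks <- list()
  for (ph in phenotypes) {
    y <- persons[[.pheno_columns[[ph]]]]
    fit <- fit_interaction(y, s, persons$birth_year, persons$household_id)
    sx <- if (reliability < 1) {
      simex_correct(y, s, persons$birth_year,
                    sigma2_err = (1 - reliability) / reliability,
                    lambda_grid = simex_lambda, B = simex_B,
                    seed = seed + match(ph, names(.pheno_columns)))
    } else NULL
    vr <- variance_by_cohort(s, persons$birth_year, var_bins)
    ok <- !is.na(y)
    bm <- binned_means(s[ok], persons$birth_year[ok],
                       standardize(y[ok], ph), fig_bins)
    blocks[[ph]] <- list(
      fit = list(coefficients = as.list(fit$coefficients),
                 se_classical = as.list(fit$se_classical),
                 pvalues_classical = as.list(fit$pvalues_classical),
                 se_cluster = as.list(fit$se_cluster),
                 pvalues_cluster = as.list(fit$pvalues_cluster),
                 n_obs = fit$n_obs, n_clusters = fit$n_clusters,
                 birth_year_center = fit$center),
      simex = if (is.null(sx)) NULL else
        list(naive = sx$naive, corrected = sx$corrected,
             lambda_grid = sx$lambda_grid, b_at_lambda = sx$b_at_lambda,
             sigma2_err = sx$sigma2_err, B = sx$B),
      variance = list(bins = vr$bins, bf_stat = vr$bf_stat,
                      bf_pvalue = vr$bf_pvalue, slope = vr$slope,
                      slope_pvalue = vr$slope_pvalue),
      binned_means = lapply(bm, as.data.frame)
    )
  }

  report <- structure(
    list(meta = list(n_samples = length(panel$sample_ids),
                     n_variants = nrow(panel$variants),
                     k_pcs = k_pcs, reliability = reliability,
                     seed = as.integer(seed),
                     phenotypes = phenotypes),
         match_report = m$report,
         results = blocks),
    class = "pgs_trend_report"
  )
  if (!is.null(out)) {
    jsonlite::write_json(unclass(report), out, auto_unbox = TRUE,
                         digits = NA, null = "null", dataframe = "columns",
                         pretty = TRUE)
  }
  report
}

#' @export
print.pgs_trend_report <- function(x, ...) {
  cat(sprintf("<pgs_trend_report> %d samples, %d variants, %d matched\n",
              x$meta$n_samples, x$meta$n_variants,
              x$match_report$n_matched))
  for (ph in names(x$results)) {
    b <- x$results[[ph]]
    bi <- b$fit$coefficients[["score:byear_c"]]
    pc <- b$fit$pvalues_classical[["score:byear_c"]]
    ph_line <- sprintf("  %-7s b_int = %+.5f (p = %.3g", ph, bi, pc)
    if (!is.null(b$fit$pvalues_cluster)) {
      ph_line <- paste0(ph_line, sprintf(
        ", cluster p = %.3g", b$fit$pvalues_cluster[["score:byear_c"]]))
    }
    ph_line <- paste0(ph_line, ")")
    if (!is.null(b$simex)) {
      ph_line <- paste0(ph_line,
                        sprintf("  SIMEX %+.5f", b$simex$corrected))
    }
    ph_line <- paste0(ph_line, sprintf("  var-stab p = %.3g",
                                       b$variance$bf_pvalue))
    cat(ph_line, "\n")
  }
  invisible(x)
}
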