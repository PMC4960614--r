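# The birth-cohort penetrance model: OLS of phenotype on score, centered
# birth year and their interaction, with classical and household-clustered
# covariance, plus the score-variance-by-cohort stability check.

#' Fit the score-by-birth-year interaction model
#'
#' Ordinary least squares of
#' `y = alpha + b_pgs * S + b_year * c + b_int * S * c + e`,
#' with `S` the (standardized) polygenic score and `c` the birth year
#' centered at its sample mean.  `b_int` — the change in the score's effect
#' per year of birth — is the quantity of interest and is invariant to the
#' centering constant.  Continuous, binary (linear-probability) and
#' log-transformed outcomes are all fitted with the same linear model so
#' coefficients stay comparable across phenotypes.
#'
#' @param phenotype,score,birth_year equal-length numeric vectors;
#'   observations with any NA are dropped.
#' @param household_id optional cluster labels; when supplied the fit also
#'   carries the household-clustered covariance and p-values from
#'   [cluster_robust_vcov()].
#' @return an object of class `trend_fit`: `coefficients` (named
#'   `(Intercept)`, `score`, `byear_c`, `score:byear_c`), `vcov_classical`,
#'   `se_classical`, `pvalues_classical`, optionally `vcov_cluster` /
#'   `se_cluster` / `pvalues_cluster` / `n_clusters`, `sigma2`, `n_obs`,
#'   `center` (the birth-year centering constant), and the design matrix /
#'   residuals needed by downstream corrections.
#' @examples
#' n <- 200; s <- rnorm(n); by <- sample(1919:1955, n, TRUE)
#' y <- 0.3 * s + 0.02 * s * (by - 1937) + rnorm(n)
#' fit_interaction(y, s, by)
#' @export
fit_interaction <- function(phenotype, score, birth_year,
                            household_id = NULL) {
  n_in <- length(phenotype)
  if (length(score) != n_in || length(birth_year) != n_in) {
    stop("phenotype, score and birth_year must have equal length",
         call. = FALSE)
  }
  if (!is.null(household_id) && length(household_id) != n_in) {
    stop("household_id length must match observations", call. = FALSE)
  }
  ok <- complete.cases(phenotype, score, birth_year)
  if (!is.null(household_id)) ok <- ok & !is.na(household_id)
  y <- phenotype[ok]; s <- score[ok]; by <- birth_year[ok]
  hh <- if (is.null(household_id)) NULL else household_id[ok]
  n <- length(y)
  if (n < 10) stop("need at least 10 complete observations", call. = FALSE)

  center <- mean(by)
  cc <- by - center
  x <- cbind("(Intercept)" = 1, score = s, byear_c = cc,
             "score:byear_c" = s * cc)
  k <- ncol(x)
  qx <- qr(x)
  if (qx$rank < k) stop("rank-deficient design matrix", call. = FALSE)
  beta <- qr.coef(qx, y)
  resid <- y - drop(x %*% beta)
  rss <- sum(resid^2)
  sigma2 <- rss / (n - k)
  xtx_inv <- chol2inv(qr.R(qx))
  dimnames(xtx_inv) <- list(colnames(x), colnames(x))
  vcov_cl <- sigma2 * xtx_inv
  se_cl <- sqrt(diag(vcov_cl))
  p_cl <- 2 * pt(-abs(beta / se_cl), df = n - k)

  fit <- structure(
    list(coefficients = beta, vcov_classical = vcov_cl, se_classical = se_cl,
         pvalues_classical = p_cl, sigma2 = sigma2, n_obs = n,
         df_residual = n - k, center = center,
         X = x, residuals = resid, xtx_inv = xtx_inv,
         household_id = hh),
    class = "trend_fit"
  )
  if (!is.null(hh)) {
    fit$vcov_cluster <- cluster_robust_vcov(fit, hh)
    fit$se_cluster <- sqrt(diag(fit$vcov_cluster))
    g <- length(unique(hh))
    fit$n_clusters <- g
    fit$pvalues_cluster <- 2 * pt(-abs(beta / fit$se_cluster), df = g - 1)
  }
  fit
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit> n = %d, birth year centered at %.2f\n",
              x$n_obs, x$center))
  tab <- data.frame(estimate = x$coefficients, se = x$se_classical,
                    p = format.pval(x$pvalues_classical, digits = 3))
  if (!is.null(x$se_cluster)) {
    tab$se_cluster <- x$se_cluster
    tab$p_cluster <- format.pval(x$pvalues_cluster, digits = 3)
  }
  print(tab, digits = 4)
  invisible(x)
}

#' @method coef trend_fit
#' @export
coef.trend_fit <- function(object, ...) object$coefficients

#' Household-clustered (Huber-White) covariance
#'
#' Sandwich estimator
#' `(X'X)^-1 (sum_g X_g' u_g u_g' X_g) (X'X)^-1` over clusters `g`, with the
#' CR1 small-sample factor `G/(G-1) * (n-1)/(n-k)`.  With every cluster a
#' singleton this reduces to the HC1-style heteroskedasticity-robust
#' covariance.  Accounts for the non-independence of spouses sharing a
#' household.
#'
#' @param fit a `trend_fit` (stores its design matrix and residuals).
#' @param household_id cluster labels, one per fitted observation; at least
#'   2 distinct clusters.
#' @return a k x k covariance matrix.
#' @export
cluster_robust_vcov <- function(fit, household_id) {
  x <- fit$X
  u <- fit$residuals
  n <- nrow(x); k <- ncol(x)
  if (length(household_id) != n) {
    stop("household_id length must match fitted observations", call. = FALSE)
  }
  g_idx <- factor(household_id)
  g <- nlevels(g_idx)
  if (g < 2) stop("need at least 2 clusters", call. = FALSE)
  # score contribution X_g' u_g per cluster, summed as crossprod
  xu <- rowsum(x * u, g_idx)
  meat <- crossprod(xu)
  adj <- g / (g - 1) * (n - 1) / (n - k)
  v <- adj * fit$xtx_inv %*% meat %*% fit$xtx_inv
  dimnames(v) <- dimnames(fit$vcov_classical)
  (v + t(v)) / 2
}

#' Score-variance stability across birth cohorts
#'
#' Cuts birth years into `n_bins` equal-frequency bins, reports the score
#' variance per bin, tests homogeneity of variances with the Brown-Forsythe
#' statistic (one-way ANOVA on absolute deviations from bin medians — robust
#' to non-normal scores), and supplements it with the OLS slope of squared
#' deviations from the overall mean on centered birth year, a
#' trend-sensitive check.  A flat variance profile supports reading a
#' changing score-phenotype association as gene-by-environment interaction
#' rather than drifting genetic variance (differential fertility or
#' assortative mating).
#'
#' @param score,birth_year equal-length numeric vectors.
#' @param n_bins number of cohort bins (>= 2, default 8); every bin must
#'   hold at least 10 observations.
#' @return an object of class `cohort_variance_report`: `bins` (data.frame
#'   with `bin`, `year_min`, `year_max`, `n`, `variance`), `bf_stat`,
#'   `bf_df`, `bf_pvalue`, `slope`, `slope_se`, `slope_pvalue`.
#' @export
variance_by_cohort <- function(score, birth_year, n_bins = 8) {
  if (length(score) != length(birth_year)) {
    stop("score and birth_year must have equal length", call. = FALSE)
  }
  ok <- complete.cases(score, birth_year)
  score <- score[ok]; birth_year <- birth_year[ok]
  n <- length(score)
  if (n_bins < 2) stop("n_bins must be >= 2", call. = FALSE)
  bin <- ceiling(rank(birth_year, ties.method = "first") * n_bins / n)
  counts <- tabulate(bin, n_bins)
  if (any(counts < 10)) {
    stop("each cohort bin must hold at least 10 observations", call. = FALSE)
  }
  if (stats::sd(score) == 0) {
    stop("constant score: variance homogeneity test degenerate",
         call. = FALSE)
  }

  bins <- data.frame(
    bin = seq_len(n_bins),
    year_min = vapply(split(birth_year, bin), min, numeric(1)),
    year_max = vapply(split(birth_year, bin), max, numeric(1)),
    n = counts,
    variance = vapply(split(score, bin), var, numeric(1))
  )
  rownames(bins) <- NULL

  # Brown-Forsythe: ANOVA F on |score - median(bin)|
  z <- abs(score - vapply(split(score, bin), median, numeric(1))[bin])
  zbar <- mean(z)
  zbar_g <- vapply(split(z, bin), mean, numeric(1))
  ss_between <- sum(counts * (zbar_g - zbar)^2)
  ss_within <- sum((z - zbar_g[bin])^2)
  df1 <- n_bins - 1; df2 <- n - n_bins
  if (ss_within == 0) {
    stop("degenerate variance test: no within-bin deviation", call. = FALSE)
  }
  bf_stat <- (ss_between / df1) / (ss_within / df2)
  bf_p <- pf(bf_stat, df1, df2, lower.tail = FALSE)

  # trend supplement: squared deviations on centered birth year
  dev2 <- (score - mean(score))^2
  cc <- birth_year - mean(birth_year)
  sl <- lm(dev2 ~ cc)
  sl_sum <- summary(sl)$coefficients
  structure(
    list(bins = bins, bf_stat = bf_stat, bf_df = c(df1, df2),
         bf_pvalue = bf_p,
         slope = unname(sl_sum["cc", "Estimate"]),
         slope_se = unname(sl_sum["cc", "Std. Error"]),
         slope_pvalue = unname(sl_sum["cc", "Pr(>|t|)"])),
    class = "cohort_variance_report"
  )
}

#' @export
print.cohort_variance_report <- function(x, ...) {
  cat("<cohort_variance_report>\n")
  print(x$bins, digits = 4)
  cat(sprintf("Brown-Forsythe F(%d, %d) = %.3f, p = %.4g\n",
              x$bf_df[1], x$bf_df[2], x$bf_stat, x$bf_pvalue))
  cat(sprintf("squared-deviation slope per year = %.3g (p = %.4g)\n",
              x$slope, x$slope_pvalue))
  invisible(x)
}
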