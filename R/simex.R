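# SIMEX: simulation-extrapolation correction of the interaction estimate
# for classical measurement error in the polygenic score.

#' SIMEX correction of the score-by-birth-year interaction
#'
#' A polygenic score built from noisy published weights measures the true
#' genetic propensity with classical error, which attenuates regression
#' coefficients toward zero.  SIMEX estimates the error-free coefficient by
#' making the problem deliberately worse: for each multiplier `lambda` in
#' `lambda_grid`, `B` replicate scores with additional
#' `Normal(0, lambda * sigma2_err)` noise are refitted and the interaction
#' coefficient averaged; a quadratic in `lambda` is then fitted through the
#' naive point (`lambda = 0`) and the averaged points, and evaluated at
#' `lambda = -1`, the extrapolation to zero measurement error.
#'
#' @param phenotype,score,birth_year as in [fit_interaction()].
#' @param sigma2_err assumed measurement-error variance of `score` (> 0); for
#'   a score standardized on the true-score scale with reliability `r`, use
#'   `(1 - r) / r`.
#' @param lambda_grid strictly increasing positive multipliers, length >= 3
#'   (default `c(0.5, 1, 1.5, 2)`) so the quadratic is over-determined.
#' @param B replicates per lambda (>= 50, default 100).
#' @param seed integer seed; the result is deterministic given it.
#' @return an object of class `simex_result`: `naive` (the lambda = 0
#'   interaction estimate), `corrected` (the extrapolated estimate),
#'   `lambda_grid`, `b_at_lambda` (mean interaction coefficient at each
#'   lambda), `extrapolation` (quadratic coefficients in lambda), `B`,
#'   `sigma2_err`, `seed`.
#' @examples
#' n <- 500; s <- rnorm(n); by <- sample(1919:1955, n, TRUE)
#' y <- 0.3 * s + 0.02 * s * (by - 1937) + rnorm(n)
#' w <- s + rnorm(n, 0, 0.5)
#' simex_correct(y, w, by, sigma2_err = 0.25, seed = 1)
#' @export
simex_correct <- function(phenotype, score, birth_year, sigma2_err,
                          lambda_grid = c(0.5, 1, 1.5, 2), B = 100,
                          seed = 1L) {
  if (!is.finite(sigma2_err) || sigma2_err <= 0) {
    stop("sigma2_err must be > 0", call. = FALSE)
  }
  if (length(lambda_grid) < 3) {
    stop("lambda_grid must hold at least 3 values", call. = FALSE)
  }
  if (any(lambda_grid <= 0) || any(diff(lambda_grid) <= 0)) {
    stop("lambda_grid must be strictly increasing and positive",
         call. = FALSE)
  }
  if (B < 50) stop("B must be >= 50", call. = FALSE)

  naive <- unname(coef(fit_interaction(phenotype, score, birth_year))[
    "score:byear_c"])
  n <- length(score)
  b_mean <- with_seed(as.integer(seed), {
    vapply(lambda_grid, function(lam) {
      sd_add <- sqrt(lam * sigma2_err)
      reps <- vapply(seq_len(B), function(b) {
        w <- score + rnorm(n, 0, sd_add)
        unname(coef(fit_interaction(phenotype, w, birth_year))[
          "score:byear_c"])
      }, numeric(1))
      mean(reps)
    }, numeric(1))
  })

  lam_all <- c(0, lambda_grid)
  b_all <- c(naive, b_mean)
  quad <- lm(b_all ~ lam_all + I(lam_all^2))
  co <- unname(coef(quad))
  corrected <- co[1] - co[2] + co[3]  # quadratic at lambda = -1

  structure(
    list(naive = naive, corrected = corrected, lambda_grid = lambda_grid,
         b_at_lambda = b_mean, extrapolation = co, B = as.integer(B),
         sigma2_err = sigma2_err, seed = as.integer(seed)),
    class = "simex_result"
  )
}

#' @export
print.simex_result <- function(x, ...) {
  cat(sprintf(
    "<simex_result> naive b_int = %.5g, corrected (lambda = -1) = %.5g\n",
    x$naive, x$corrected))
  cat(sprintf("  sigma2_err = %.4g, B = %d per lambda\n",
              x$sigma2_err, x$B))
  print(data.frame(lambda = x$lambda_grid, b_int = x$b_at_lambda),
        digits = 5)
  invisible(x)
}
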