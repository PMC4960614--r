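# Cohort-figure summaries: binned means by score sign across birth-year
# rank bins, and fitted penetrance lines at +/- 1 SD of the score.

#' Binned means by score sign across birth-year bins
#'
#' Splits the sample at score 0 (exact zeros join the "below" group —
#' measure-zero for continuous scores), ranks each group by birth year, cuts
#' the ranks into `n_bins` contiguous blocks of near-equal size (any
#' remainder spread over the earliest bins; birth-year ties broken by
#' response value so results do not depend on row order), and
#' returns each block's mean birth year, mean response and size.  The
#' size-weighted mean of bin means reproduces the group mean exactly, and
#' the output is invariant to input row order.
#'
#' @param score standardized score vector.
#' @param birth_year,response equal-length numeric vectors.
#' @param n_bins bins per group (>= 2, default 20); each group must hold at
#'   least `n_bins` observations.
#' @return named list of two `binned_summary` data.frames (`below`,
#'   `above`), each with columns `bin`, `mean_birth_year`, `mean_response`,
#'   `n`, rows ordered by mean birth year.
#' @export
binned_means <- function(score, birth_year, response, n_bins = 20) {
  n <- length(score)
  if (length(birth_year) != n || length(response) != n) {
    stop("inputs must have equal length", call. = FALSE)
  }
  if (n_bins < 2 && n_bins != 1) {
    stop("n_bins must be >= 2 (or 1 for a single summary point)",
         call. = FALSE)
  }
  ok <- complete.cases(score, birth_year, response)
  score <- score[ok]; birth_year <- birth_year[ok]; response <- response[ok]

  one_group <- function(by, resp, label) {
    m <- length(by)
    if (m < n_bins) {
      stop(sprintf("group '%s' has %d observations, fewer than %d bins",
                   label, m, n_bins), call. = FALSE)
    }
    ord <- order(by, resp)  # birth-year sort, ties by response value
    base <- m %/% n_bins
    extra <- m %% n_bins
    sizes <- rep(base, n_bins) + c(rep(1L, extra), rep(0L, n_bins - extra))
    bin <- rep(seq_len(n_bins), times = sizes)
    out <- data.frame(
      bin = seq_len(n_bins),
      mean_birth_year = vapply(split(by[ord], bin), mean, numeric(1)),
      mean_response = vapply(split(resp[ord], bin), mean, numeric(1)),
      n = sizes
    )
    rownames(out) <- NULL
    class(out) <- c("binned_summary", "data.frame")
    out
  }

  below <- score <= 0
  list(below = one_group(birth_year[below], response[below], "score <= 0"),
       above = one_group(birth_year[!below], response[!below], "score > 0"))
}

#' Fitted penetrance lines at +/- 1 SD of the score
#'
#' Evaluates the interaction model's predictions at standardized score +1
#' and -1 across a birth-year grid.  The vertical gap between the two lines
#' at centered birth year `c` is exactly `2 * (b_pgs + b_int * c)`: parallel
#' lines mean no penetrance trend, a widening gap means the score grows more
#' predictive in later cohorts.
#'
#' @param fit a `trend_fit` from [fit_interaction()].
#' @param birth_year_grid numeric vector of birth years at which to predict.
#' @return data.frame with columns `birth_year`, `pred_lower` (score = -1),
#'   `pred_upper` (score = +1), `gap`.
#' @export
fitted_lines <- function(fit, birth_year_grid) {
  b <- fit$coefficients
  cc <- birth_year_grid - fit$center
  pred_at <- function(s) {
    b[["(Intercept)"]] + b[["score"]] * s + b[["byear_c"]] * cc +
      b[["score:byear_c"]] * s * cc
  }
  up <- pred_at(1); lo <- pred_at(-1)
  data.frame(birth_year = birth_year_grid, pred_lower = lo, pred_upper = up,
             gap = up - lo)
}

#' Plot the cohort-penetrance figure for one phenotype
#'
#' Two fitted lines (score = +/- 1 SD) over the birth-year range and the
#' binned mean clouds for the below-0 and above-0 score groups.  The
#' response is standardized within the routine so phenotypes plot on a
#' comparable scale.
#'
#' @param fit a `trend_fit` fitted on the standardized response.
#' @param score,birth_year,response the data behind the fit (response on its
#'   original scale; standardized internally).
#' @param n_bins bins per score-sign group (default 20).
#' @param main plot title.
#' @return invisibly, the [binned_means()] output used for the points.
#' @export
plot_penetrance <- function(fit, score, birth_year, response, n_bins = 20,
                            main = "") {
  resp_std <- standardize(response, "response")
  bm <- binned_means(score, birth_year, resp_std, n_bins)
  grid <- seq(min(birth_year), max(birth_year), length.out = 100)
  fl <- fitted_lines(fit, grid)
  ylim <- range(fl$pred_lower, fl$pred_upper,
                bm$below$mean_response, bm$above$mean_response)
  plot(grid, fl$pred_upper, type = "l", col = "grey50", lwd = 2,
       xlab = "birth year", ylab = "standardized response",
       ylim = ylim, main = main)
  graphics::lines(grid, fl$pred_lower, col = "black", lwd = 2)
  graphics::points(bm$above$mean_birth_year, bm$above$mean_response,
                   pch = 16, col = "grey50")
  graphics::points(bm$below$mean_birth_year, bm$below$mean_response,
                   pch = 16, col = "black")
  graphics::legend("topleft", bty = "n", lwd = c(2, 2), pch = c(16, 16),
                   col = c("grey50", "black"),
                   legend = c("score +1 SD / above 0", "score -1 SD / below 0"))
  invisible(bm)
}
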