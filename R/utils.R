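# Internal helpers shared across modules.

#' Standardize a numeric vector to mean 0, SD 1
#'
#' @param x numeric vector without NAs.
#' @param what label used in the zero-variance error message.
#' @return `(x - mean(x)) / sd(x)`.
#' @keywords internal
#' @noRd
standardize <- function(x, what = "score") {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop(sprintf("cannot standardize %s: zero variance", what), call. = FALSE)
  }
  (x - mean(x)) / s
}

# Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG state
# afterwards so library functions never clobber a user's random stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

stopifnot_scalar_count <- function(x, name) {
  if (length(x) != 1 || is.na(x) || x != as.integer(x) || x <= 0) {
    stop(sprintf("'%s' must be a single positive integer", name), call. = FALSE)
  }
}
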