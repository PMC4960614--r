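# Population-structure adjustment: genotype PCA on a reference subgroup and
# residualization of scores on the top components.

#' Genotype principal components from a reference subgroup
#'
#' Reference-sample dosages are centered by `2 * p` and scaled by
#' `sqrt(2 p (1 - p))`, with `p` the alt-allele frequency estimated in the
#' reference (PLINK-style variance scaling); variants monomorphic in the
#' reference are dropped.  The top-k right singular vectors of the
#' reference matrix define the loadings, and ALL samples — reference or not
#' — are projected onto them, mirroring the practice of computing components
#' in a genetically homogeneous subgroup and applying them to everyone
#' scored.  Missing dosages are mean-imputed (zero after centering).  Each
#' component's sign is fixed so its largest-magnitude loading is positive.
#'
#' @param panel a [genotype_panel()].
#' @param reference_mask logical vector over samples selecting the reference
#'   subgroup (default: all samples); must select at least `k + 1`.
#' @param k number of components (default 10).
#' @return an object of class `pc_projection`: `loadings` (kept variants x
#'   k), `coords` (all samples x k), `sdev` (singular values / sqrt(n_ref -
#'   1)), `k`, `reference_mask`, `variant_ids` (kept), `center`, `scale`.
#' @export
compute_pcs <- function(panel, reference_mask = NULL, k = 10) {
  n <- length(panel$sample_ids)
  if (is.null(reference_mask)) reference_mask <- rep(TRUE, n)
  if (length(reference_mask) != n || !is.logical(reference_mask)) {
    stop("reference_mask must be a logical vector over samples",
         call. = FALSE)
  }
  n_ref <- sum(reference_mask)
  if (n_ref == 0) stop("empty reference subgroup", call. = FALSE)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (n_ref < k + 1) {
    stop(sprintf("reference subgroup (%d) must exceed k (%d)", n_ref, k),
         call. = FALSE)
  }

  x_ref <- panel$dosages[reference_mask, , drop = FALSE]
  p_hat <- colMeans(x_ref, na.rm = TRUE) / 2
  keep <- is.finite(p_hat) & p_hat > 0 & p_hat < 1
  if (!any(keep)) stop("all variants monomorphic in reference", call. = FALSE)
  p_hat <- p_hat[keep]
  ctr <- 2 * p_hat
  scl <- sqrt(2 * p_hat * (1 - p_hat))

  zscore <- function(x) {
    z <- sweep(sweep(x[, keep, drop = FALSE], 2, ctr), 2, scl, "/")
    z[is.na(z)] <- 0
    z
  }
  z_ref <- zscore(x_ref)
  sv <- svd(z_ref, nu = 0, nv = min(dim(z_ref)))
  tol <- max(dim(z_ref)) * max(sv$d) * .Machine$double.eps
  rank <- sum(sv$d > tol)
  if (k > rank) {
    stop(sprintf("k = %d exceeds reference matrix rank %d", k, rank),
         call. = FALSE)
  }
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  # deterministic sign: largest-|loading| entry positive per component
  for (j in seq_len(k)) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) loadings[, j] <- -loadings[, j]
  }
  coords <- zscore(panel$dosages) %*% loadings
  dimnames(loadings) <- list(panel$variants$id[keep], paste0("PC", 1:k))
  dimnames(coords) <- list(panel$sample_ids, paste0("PC", 1:k))
  structure(
    list(loadings = loadings, coords = coords,
         sdev = sv$d[seq_len(k)] / sqrt(max(1, n_ref - 1)),
         k = k, reference_mask = reference_mask,
         variant_ids = panel$variants$id[keep],
         center = ctr, scale = scl),
    class = "pc_projection"
  )
}

#' @export
print.pc_projection <- function(x, ...) {
  cat(sprintf("<pc_projection> k = %d, %d reference samples, %d variants\n",
              x$k, sum(x$reference_mask), length(x$variant_ids)))
  invisible(x)
}

#' Residualize a score on principal components
#'
#' Ordinary least squares of the standardized score on an intercept plus the
#' k sample coordinates; the residuals (orthogonal to every component) are
#' re-standardized to mean 0, SD 1.  With `proj = NULL` or `k = 0` the
#' operation is the identity on standardized scores.  Applying the
#' operation twice equals applying it once.
#'
#' @param scores a [score_vector()].
#' @param proj a `pc_projection` from [compute_pcs()] (or NULL).
#' @return a [score_vector()] whose `raw` slot holds the residuals and `std`
#'   their standardization.  Collinear components or a zero-variance
#'   residual raise errors.
#' @export
residualize <- function(scores, proj) {
  if (is.null(proj) || proj$k == 0) {
    return(score_vector(scores$sample_ids, scores$std, scores$std,
                        scores$n_variants_used))
  }
  if (nrow(proj$coords) != length(scores$std)) {
    stop("scores and projection cover different samples", call. = FALSE)
  }
  x <- cbind(1, proj$coords)
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    stop("collinear principal components: cannot residualize", call. = FALSE)
  }
  res <- qr.resid(qx, scores$std)
  # the input is standardized (SD 1), so a residual SD this small means the
  # score lies in the span of the components
  if (stats::sd(res) < 1e-8) {
    stop("cannot standardize residualized score: zero variance",
         call. = FALSE)
  }
  std <- standardize(res, "residualized score")
  score_vector(scores$sample_ids, res, std, scores$n_variants_used)
}
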