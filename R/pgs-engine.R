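# Polygenic score construction: allele matching with strand-ambiguity
# filtering, then a weighted sum of effect-allele dosages.

#' Match GWAS weight records against a genotype panel
#'
#' Records are joined to panel variants by id and classified in a fixed
#' order:
#' \enumerate{
#'   \item strand-ambiguous allele pairs (A/T or C/G) are removed — the
#'     effect allele cannot be resolved from labels alone;
#'   \item ids absent from the panel are dropped as unmatched;
#'   \item records whose effect allele equals the panel ALT (and other
#'     allele the REF) use the dosage as-is;
#'   \item records whose effect allele equals the panel REF (and other
#'     allele the ALT) are kept with a recorded flip — their effective
#'     dosage downstream is `2 - x`;
#'   \item anything else is an allele mismatch and is dropped.
#' }
#' No p-value filtering is ever applied: weakly associated variants carry
#' small weights and down-weight themselves.
#'
#' @param panel a [genotype_panel()].
#' @param weights a [gwas_weights()] table; duplicate variant ids are an
#'   error naming the id.
#' @return a list with `matched` (data.frame `snp`, `beta`, `flipped`) and
#'   `report` (counts: `n_input_weights`, `n_matched`, `n_ambiguous_removed`,
#'   `n_allele_mismatch`, `n_unmatched_id`, `n_flipped`; the first four plus
#'   unmatched sum to the input count).
#' @export
match_variants <- function(panel, weights) {
  dup <- weights$snp[duplicated(weights$snp)]
  if (length(dup)) {
    stop(sprintf("duplicate variant id(s) in weights: %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  n_in <- nrow(weights)
  amb <- is_ambiguous_pair(weights$effect_allele, weights$other_allele)

  idx <- match(weights$snp, panel$variants$id)
  in_panel <- !is.na(idx)
  ref <- panel$variants$ref[idx]
  alt <- panel$variants$alt[idx]

  status <- rep("mismatch", n_in)
  status[!amb & in_panel &
           weights$effect_allele == alt & weights$other_allele == ref] <-
    "match"
  status[!amb & in_panel &
           weights$effect_allele == ref & weights$other_allele == alt] <-
    "flip"
  status[!amb & !in_panel] <- "unmatched"
  status[amb] <- "ambiguous"

  keep <- status %in% c("match", "flip")
  matched <- data.frame(snp = weights$snp[keep],
                        beta = weights$beta[keep],
                        flipped = status[keep] == "flip",
                        stringsAsFactors = FALSE)
  report <- list(
    n_input_weights = n_in,
    n_matched = sum(keep),
    n_ambiguous_removed = sum(status == "ambiguous"),
    n_allele_mismatch = sum(status == "mismatch"),
    n_unmatched_id = sum(status == "unmatched"),
    n_flipped = sum(status == "flip")
  )
  list(matched = matched, report = report)
}

#' Compute polygenic scores from matched weights
#'
#' The raw score of sample i is `sum_j d_ij * w_j` over matched variants,
#' where `d` is the orientation-corrected dosage (`2 - x` for flipped
#' records).  Missing dosages are imputed with the variant's mean observed
#' dosage (2 * alt-allele frequency) before orientation so every sample gets
#' a score.  The raw vector is then standardized to mean 0, SD 1.
#'
#' @param panel a [genotype_panel()].
#' @param matched the `matched` data.frame from [match_variants()] (or any
#'   data.frame with `snp`, `beta`, `flipped`).
#' @return a [score_vector()].  Zero matched weights or a zero-variance raw
#'   score (standardization undefined) raise errors.
#' @examples
#' sim <- simulate_panel(sim_config(n_samples = 30, n_variants = 12,
#'                                  ambiguous_fraction = 0, seed = 2))
#' m <- match_variants(sim$panel, sim$weights)
#' compute_scores(sim$panel, m$matched)
#' @export
compute_scores <- function(panel, matched) {
  if (nrow(matched) == 0) {
    stop("no matched weights: cannot compute scores", call. = FALSE)
  }
  j <- match(matched$snp, panel$variants$id)
  if (anyNA(j)) {
    stop("matched weights refer to variants absent from panel",
         call. = FALSE)
  }
  d <- panel$dosages[, j, drop = FALSE]
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    nas <- which(is.na(d), arr.ind = TRUE)
    d[nas] <- mu[nas[, 2]]
  }
  flip <- matched$flipped
  if (any(flip)) d[, flip] <- 2 - d[, flip, drop = FALSE]
  raw <- drop(d %*% matched$beta)
  std <- standardize(raw, "polygenic score")
  score_vector(panel$sample_ids, raw, std, nrow(matched))
}

#' Score a VCF against a weights file in one call
#'
#' Convenience wrapper: read, match, score.
#'
#' @param vcf_path,weights_path input files.
#' @return list with `scores` ([score_vector()]) and `report` (match report).
#' @export
score_files <- function(vcf_path, weights_path) {
  panel <- read_panel(vcf_path)
  w <- read_weights(weights_path)
  m <- match_variants(panel, w)
  list(scores = compute_scores(panel, m$matched), report = m$report)
}
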