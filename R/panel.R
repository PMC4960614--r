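# Core containers: genotype panel, GWAS weight table, score vector.

#' Construct a genotype panel
#'
#' A genotype panel is a samples-by-variants dosage matrix counting ALT
#' alleles (0, 1, 2 or NA) together with per-variant metadata.
#'
#' @param dosages numeric matrix, samples in rows, variants in columns;
#'   entries must be 0, 1, 2 or NA.
#' @param variants data.frame with columns `id`, `ref`, `alt` and optionally
#'   `pos`, one row per dosage column, ids unique.
#' @param sample_ids character vector, one per dosage row.
#' @param subpop optional integer vector of subpopulation labels (simulation
#'   bookkeeping).
#' @return an object of class `genotype_panel`.
#' @export
genotype_panel <- function(dosages, variants, sample_ids,
                           subpop = NULL) {
  dosages <- as.matrix(dosages)
  if (nrow(variants) != ncol(dosages)) {
    stop("variants table and dosage columns disagree", call. = FALSE)
  }
  if (length(sample_ids) != nrow(dosages)) {
    stop("sample_ids and dosage rows disagree", call. = FALSE)
  }
  if (anyDuplicated(variants$id)) {
    stop("variant ids must be unique", call. = FALSE)
  }
  ok <- dosages %in% c(0, 1, 2) | is.na(dosages)
  if (!all(ok)) {
    stop("dosages must be 0, 1, 2 or missing", call. = FALSE)
  }
  rownames(dosages) <- sample_ids
  colnames(dosages) <- variants$id
  structure(
    list(dosages = dosages,
         variants = as.data.frame(variants, stringsAsFactors = FALSE),
         sample_ids = as.character(sample_ids),
         subpop = subpop),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %d samples x %d variants (%.1f%% missing)\n",
              length(x$sample_ids), nrow(x$variants),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$dosages)

#' Construct a GWAS weight table
#'
#' One record per variant: the effect allele (the allele the published beta
#' counts), the other allele, and the effect size, with optional standard
#' error and p-value.
#'
#' @param snp character variant ids.
#' @param effect_allele,other_allele single bases A/C/G/T; must differ
#'   within a record.
#' @param beta numeric effect sizes (phenotype units per effect allele).
#' @param se,pval optional numeric vectors (NA allowed).
#' @return a data.frame of class `gwas_weights`.
#' @export
gwas_weights <- function(snp, effect_allele, other_allele, beta,
                         se = NA_real_, pval = NA_real_) {
  effect_allele <- toupper(effect_allele)
  other_allele <- toupper(other_allele)
  bases <- c("A", "C", "G", "T")
  if (!all(effect_allele %in% bases) || !all(other_allele %in% bases)) {
    stop("alleles must be single bases A/C/G/T", call. = FALSE)
  }
  if (any(effect_allele == other_allele)) {
    stop("effect_allele must differ from other_allele", call. = FALSE)
  }
  bad_p <- !is.na(pval) & (pval < 0 | pval > 1)
  if (any(bad_p)) stop("p-values must lie in [0, 1]", call. = FALSE)
  se <- rep_len(as.numeric(se), length(snp))
  pval <- rep_len(as.numeric(pval), length(snp))
  out <- data.frame(snp = as.character(snp),
                    effect_allele = effect_allele,
                    other_allele = other_allele,
                    beta = as.numeric(beta),
                    se = as.numeric(se),
                    pval = as.numeric(pval),
                    stringsAsFactors = FALSE)
  class(out) <- c("gwas_weights", "data.frame")
  out
}

#' Construct a score vector
#'
#' @param sample_ids character ids, one per sample.
#' @param raw raw (summed) scores.
#' @param std standardized scores (mean 0, SD 1).
#' @param n_variants_used number of weight records that contributed.
#' @return an object of class `score_vector`.
#' @keywords internal
#' @export
score_vector <- function(sample_ids, raw, std, n_variants_used) {
  structure(
    list(sample_ids = as.character(sample_ids),
         raw = as.numeric(raw), std = as.numeric(std),
         n_variants_used = as.integer(n_variants_used)),
    class = "score_vector"
  )
}

#' @export
print.score_vector <- function(x, ...) {
  cat(sprintf(
    "<score_vector> %d samples, %d variants used; std mean %.2e, sd %.4f\n",
    length(x$raw), x$n_variants_used, mean(x$std), stats::sd(x$std)))
  invisible(x)
}

#' @export
length.score_vector <- function(x) length(x$raw)
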