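# File formats: VCF v4.2 genotypes, tab-delimited GWAS weights, wave-long
# phenotype CSV.  Writers emit plain text; the VCF reader is backed by
# VariantAnnotation so real-world files parse the same way fixtures do.

#' Write a genotype panel as VCF v4.2
#'
#' Biallelic records with a GT FORMAT field only; missing dosages become
#' `./.`.  Dosage 0/1/2 maps to `0/0`, `0/1`, `1/1` (counting ALT alleles).
#'
#' @param panel a [genotype_panel()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path) {
  v <- panel$variants
  pos <- if ("pos" %in% names(v)) v$pos else seq_len(nrow(v)) * 1000L
  gt_map <- c("0/0", "0/1", "1/1")
  dos <- panel$dosages
  gt <- matrix("./.", nrow = nrow(dos), ncol = ncol(dos))
  obs <- !is.na(dos)
  gt[obs] <- gt_map[dos[obs] + 1L]
  body <- vapply(seq_len(nrow(v)), function(j) {
    paste(c("1", pos[j], v$id[j], v$ref[j], v$alt[j], ".", ".", ".", "GT",
            gt[, j]), collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=pgstrend",
    "##contig=<ID=1>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$sample_ids), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a genotype panel from a VCF file
#'
#' Accepts biallelic SNP records with GT genotypes; multi-allelic records or
#' non-single-base alleles raise an error naming the offending record.
#'
#' @param path VCF file (plain or bgzipped).
#' @return a [genotype_panel()] with ALT-allele dosages (NA for `./.`).
#' @export
read_panel <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  alt_list <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt_list)
  if (any(n_alt != 1)) {
    bad <- which(n_alt != 1)[1]
    stop(sprintf("record %d (%s) is not biallelic", bad, rownames(vcf)[bad]),
         call. = FALSE)
  }
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt <- as.character(unlist(alt_list))
  bad_allele <- !(ref %in% c("A", "C", "G", "T")) |
    !(alt %in% c("A", "C", "G", "T"))
  if (any(bad_allele)) {
    bad <- which(bad_allele)[1]
    stop(sprintf("record %d (%s) has non-SNP alleles %s/%s",
                 bad, rownames(vcf)[bad], ref[bad], alt[bad]), call. = FALSE)
  }
  gt <- VariantAnnotation::geno(vcf)$GT  # variants x samples
  if (is.null(gt)) stop("VCF has no GT field", call. = FALSE)
  dose_of <- c("0/0" = 0, "0|0" = 0, "0/1" = 1, "1/0" = 1, "0|1" = 1,
               "1|0" = 1, "1/1" = 2, "1|1" = 2)
  dos <- matrix(dose_of[gt], nrow = nrow(gt), ncol = ncol(gt))
  unknown <- !(gt %in% c(names(dose_of), "./.", ".|.", "."))
  if (any(unknown)) {
    bad <- which(unknown, arr.ind = TRUE)[1, ]
    stop(sprintf("record %d has unparseable genotype '%s'",
                 bad[1], gt[bad[1], bad[2]]), call. = FALSE)
  }
  variants <- data.frame(
    id = rownames(vcf), ref = ref, alt = alt,
    pos = BiocGenerics::start(SummarizedExperiment::rowRanges(vcf)),
    stringsAsFactors = FALSE
  )
  genotype_panel(t(dos), variants, colnames(gt))
}

#' Write GWAS weights as tab-delimited text
#'
#' Header `snp effect_allele other_allele beta se pval`; NA written as `NA`.
#'
#' @param weights a [gwas_weights()] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(weights, path) {
  data.table::fwrite(as.data.frame(weights), path, sep = "\t", na = "NA",
                     quote = FALSE)
  invisible(path)
}

#' Read GWAS weights from tab-delimited text
#'
#' Expects the header `snp effect_allele other_allele beta se pval`
#' (`se`/`pval` optional).  Malformed alleles raise an error with the line
#' number (header is line 1).
#'
#' @param path weights TSV.
#' @return a [gwas_weights()] table; an empty-but-headered file gives zero
#'   rows.
#' @export
read_weights <- function(path) {
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = list(character = "snp"),
                           data.table = FALSE)
  need <- c("snp", "effect_allele", "other_allele", "beta")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop(sprintf("weights file lacks column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (nrow(tab) == 0) {
    return(gwas_weights(character(0), character(0), character(0), numeric(0)))
  }
  bad <- !(toupper(tab$effect_allele) %in% c("A", "C", "G", "T")) |
    !(toupper(tab$other_allele) %in% c("A", "C", "G", "T")) |
    toupper(tab$effect_allele) == toupper(tab$other_allele)
  if (any(bad)) {
    stop(sprintf("malformed alleles at line %d of %s",
                 which(bad)[1] + 1L, path), call. = FALSE)
  }
  gwas_weights(tab$snp, tab$effect_allele, tab$other_allele, tab$beta,
               se = if ("se" %in% names(tab)) tab$se else NA_real_,
               pval = if ("pval" %in% names(tab)) tab$pval else NA_real_)
}

#' Read or write a wave-long phenotype table
#'
#' CSV with header
#' `person_id household_id birth_year wave educ bmi height heart cesd`.
#'
#' @param wave_table wave-long data.frame.
#' @param path file path.
#' @return `read_wave_table`: the data.frame; `write_wave_table`: `path`,
#'   invisibly.
#' @export
write_wave_table <- function(wave_table, path) {
  data.table::fwrite(as.data.frame(wave_table), path, na = "NA",
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_wave_table
#' @export
read_wave_table <- function(path) {
  tab <- data.table::fread(path, data.table = FALSE,
                           colClasses = list(character = c("person_id",
                                                           "household_id")))
  need <- c("person_id", "household_id", "birth_year", "wave")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop(sprintf("phenotype file lacks column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  tab
}

#' Write a complete synthetic fixture to a directory
#'
#' Emits `genotypes.vcf`, `weights.tsv` and `phenotypes.csv`; the triple
#' round-trips bit-identically through [read_panel()], [read_weights()] and
#' [read_wave_table()] on ids, alleles and dosages.
#'
#' @param sim output of [simulate_panel()].
#' @param wave_table output of [simulate_phenotypes()].
#' @param dir output directory (created if needed).
#' @return named character vector of the three paths, invisibly.
#' @export
write_fixture <- function(sim, wave_table, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create directory '%s'", dir), call. = FALSE)
  }
  paths <- c(vcf = file.path(dir, "genotypes.vcf"),
             weights = file.path(dir, "weights.tsv"),
             phenotypes = file.path(dir, "phenotypes.csv"))
  write_vcf(sim$panel, paths[["vcf"]])
  write_weights(sim$weights, paths[["weights"]])
  write_wave_table(wave_table, paths[["phenotypes"]])
  invisible(paths)
}
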