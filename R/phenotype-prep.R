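# Collapse a wave-long survey table to one row per person with the five
# derived phenotypes.

#' Derive per-person phenotypes from a wave-long table
#'
#' For each person: `educ_years` is passed through (time-invariant; the
#' maximum over non-missing waves, which equals the reported value);
#' `bmi_mean` is the mean BMI over non-missing waves; `height_max` the
#' maximum height over non-missing waves; `heart_ever` is 1 if any wave
#' reports heart problems, else 0; `cesd_log` is `log(mean(cesd) + 1)` over
#' non-missing waves — the +1 keeps the log defined at zero symptoms and the
#' transform tames the right skew.  A person missing a phenotype in every
#' wave gets NA for that phenotype but is never dropped globally.  Wave
#' order never affects any derived value.
#'
#' @param wave_table data.frame with columns `person_id`, `household_id`,
#'   `birth_year`, `wave` and any of `educ`, `bmi`, `height`, `heart`,
#'   `cesd`; absent phenotype columns yield NA.
#' @return one-row-per-person data.frame (sorted by `person_id`) with
#'   columns `person_id`, `household_id`, `birth_year`, `educ_years`,
#'   `bmi_mean`, `height_max`, `heart_ever`, `cesd_log`.  Negative BMI,
#'   height or CESD values raise an error naming the person.
#' @examples
#' waves <- data.frame(person_id = "p1", household_id = "h1",
#'                     birth_year = 1940, wave = 1:4,
#'                     heart = c(0, 0, 1, 0), cesd = c(0, 2, 4, 2))
#' derive_phenotypes(waves)
#' @export
derive_phenotypes <- function(wave_table) {
  for (col in c("bmi", "height", "cesd")) {
    if (col %in% names(wave_table)) {
      neg <- !is.na(wave_table[[col]]) & wave_table[[col]] < 0
      if (any(neg)) {
        stop(sprintf("negative %s for person %s", col,
                     wave_table$person_id[which(neg)[1]]), call. = FALSE)
      }
    }
  }
  dt <- data.table::as.data.table(wave_table)
  for (col in c("educ", "bmi", "height", "heart", "cesd")) {
    val <- if (col %in% names(wave_table)) {
      as.numeric(wave_table[[col]])
    } else NA_real_
    data.table::set(dt, j = col, value = val)
  }
  # grouped aggregation stays on data.table's optimized (GForce) path;
  # all-NA groups surface as NaN / -Inf and are mapped back to NA below
  agg <- suppressWarnings(dt[
    , list(educ_years = max(educ, na.rm = TRUE),
           bmi_mean = mean(bmi, na.rm = TRUE),
           height_max = max(height, na.rm = TRUE),
           heart_ever = max(heart, na.rm = TRUE),
           cesd_mean = mean(cesd, na.rm = TRUE)),
    keyby = "person_id"])
  first_rows <- !duplicated(dt$person_id)
  idx <- match(agg$person_id, dt$person_id[first_rows])
  clean <- function(x) ifelse(is.finite(x), x, NA_real_)
  out <- data.frame(
    person_id = agg$person_id,
    household_id = dt$household_id[first_rows][idx],
    birth_year = dt$birth_year[first_rows][idx],
    educ_years = clean(agg$educ_years),
    bmi_mean = clean(agg$bmi_mean),
    height_max = clean(agg$height_max),
    heart_ever = clean(pmin(agg$heart_ever, 1)),
    cesd_log = log(clean(agg$cesd_mean) + 1),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
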