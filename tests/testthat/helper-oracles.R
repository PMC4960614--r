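# Independent oracles and tiny fixture builders used across the suite.
# Oracles are deliberately naive (double loops, explicit normal equations)
# and share no code with the implementation paths they check.

# Brute-force polygenic score: loop over samples and weight records.
oracle_score <- function(dosages, variants, matched) {
  n <- nrow(dosages)
  raw <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (r in seq_len(nrow(matched))) {
      j <- which(variants$id == matched$snp[r])
      x <- dosages[i, j]
      if (is.na(x)) x <- mean(dosages[, j], na.rm = TRUE)
      d <- if (matched$flipped[r]) 2 - x else x
      acc <- acc + d * matched$beta[r]
    }
    raw[i] <- acc
  }
  raw
}

# Rank-and-slice binned means for one score-sign group.
oracle_binned_group <- function(by, resp, n_bins) {
  ord <- order(by, resp)
  by <- by[ord]; resp <- resp[ord]
  m <- length(by)
  sizes <- rep(m %/% n_bins, n_bins)
  r <- m %% n_bins
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1
  stops <- cumsum(sizes)
  starts <- c(1, head(stops, -1) + 1)
  data.frame(
    bin = seq_len(n_bins),
    mean_birth_year = mapply(function(a, b) mean(by[a:b]), starts, stops),
    mean_response = mapply(function(a, b) mean(resp[a:b]), starts, stops),
    n = sizes
  )
}

# Hand-built panel: explicit dosage matrix and variant table.
tiny_panel <- function(dosages, ref, alt, ids = NULL) {
  dosages <- as.matrix(dosages)
  m <- ncol(dosages)
  if (is.null(ids)) ids <- paste0("v", seq_len(m))
  genotype_panel(dosages,
                 data.frame(id = ids, ref = ref, alt = alt,
                            pos = seq_len(m), stringsAsFactors = FALSE),
                 sprintf("s%02d", seq_len(nrow(dosages))))
}

# Quick wave-long table for phenotype-prep tests.
tiny_waves <- function(person_id, wave, ..., household_id = "h1",
                       birth_year = 1940) {
  data.frame(person_id = person_id, household_id = household_id,
             birth_year = birth_year, wave = wave, ...,
             stringsAsFactors = FALSE)
}

# Small standard cohort used by several files (cheap but non-degenerate).
small_cohort <- function(seed = 101, n = 400, m = 40, ...) {
  cfg <- sim_config(n_samples = n, n_variants = m, seed = seed,
                    weight_noise_sd = 0, ...)
  sim <- simulate_panel(cfg)
  waves <- simulate_phenotypes(sim$panel, sim$truth, cfg)
  list(cfg = cfg, sim = sim, waves = waves)
}
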