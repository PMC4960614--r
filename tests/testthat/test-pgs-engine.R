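test_that("allele matching classifies ambiguous, flipped and mismatched records", {
  panel <- tiny_panel(rbind(c(0, 1, 2, 1, 0),
                            c(1, 2, 0, 0, 1),
                            c(2, 0, 1, 2, 2)),
                      ref = c("A", "C", "G", "A", "C"),
                      alt = c("G", "T", "A", "C", "T"))
  w <- gwas_weights(
    snp = c("v1", "v2", "v3", "v4", "v5", "v9"),
    effect_allele = c("G", "C", "A", "A", "T", "A"),
    other_allele  = c("A", "T", "T", "C", "G", "G"),
    beta = c(0.5, -0.2, 0.3, 0.1, 0.4, 0.9)
  )
  # v1: effect = alt, no flip; v2: effect = ref -> flip; v3: A/T ambiguous;
  # v4: effect = ref but orientation reversed -> flip; v5: T/G vs panel C/T
  # mismatch; v9: absent.
  m <- match_variants(panel, w)
  expect_equal(m$report$n_input_weights, 6)
  expect_equal(m$report$n_matched, 3)
  expect_equal(m$report$n_ambiguous_removed, 1)
  expect_equal(m$report$n_allele_mismatch, 1)
  expect_equal(m$report$n_unmatched_id, 1)
  expect_equal(m$report$n_flipped, 2)
  with(m$report,
       expect_equal(n_matched + n_ambiguous_removed + n_allele_mismatch +
                      n_unmatched_id, n_input_weights))
  expect_equal(m$matched$snp, c("v1", "v2", "v4"))
  expect_equal(m$matched$flipped, c(FALSE, TRUE, TRUE))
})

test_that("duplicate weight ids raise an error naming the id", {
  panel <- tiny_panel(cbind(c(0, 1)), ref = "A", alt = "G")
  w <- gwas_weights(c("v1", "v1"), c("G", "G"), c("A", "A"), c(0.1, 0.2))
  expect_error(match_variants(panel, w), "v1")
})

test_that("flipped records use the complement dosage 2 - x", {
  panel <- tiny_panel(cbind(c(0, 1, 2)), ref = "A", alt = "G")
  w_flip <- gwas_weights("v1", "A", "G", 1)
  m <- match_variants(panel, w_flip)
  expect_true(m$matched$flipped)
  sc <- compute_scores(panel, m$matched)
  expect_equal(sc$raw, c(2, 1, 0))
})

test_that("a unit weight reproduces the dosage as the raw score", {
  panel <- tiny_panel(cbind(c(0, 1, 2)), ref = "A", alt = "G")
  m <- match_variants(panel, gwas_weights("v1", "G", "A", 1))
  expect_false(m$matched$flipped)
  expect_equal(compute_scores(panel, m$matched)$raw, c(0, 1, 2))
})

test_that("degenerate scores raise explicit errors", {
  panel <- tiny_panel(rbind(c(0, 1), c(1, 2), c(2, 0)),
                      ref = c("A", "C"), alt = c("G", "T"))
  w0 <- data.frame(snp = c("v1", "v2"), beta = c(0, 0),
                   flipped = c(FALSE, FALSE))
  expect_error(compute_scores(panel, w0), "zero variance")
  expect_error(compute_scores(panel, w0[0, ]), "no matched weights")
})

test_that("missing dosages are mean-imputed before weighting", {
  panel <- tiny_panel(cbind(c(0, 2, NA, 2)), ref = "A", alt = "G")
  m <- match_variants(panel, gwas_weights("v1", "G", "A", 0.5))
  sc <- compute_scores(panel, m$matched)
  # observed mean dosage is 4/3, so the missing entry scores (4/3) * 0.5
  expect_equal(sc$raw, c(0, 1, 4 / 3 * 0.5, 1), tolerance = 1e-12)
})

test_that("scoring equals the brute-force double-loop oracle", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(2:10, 1); m <- sample(2:10, 1)
    dos <- matrix(sample(c(0:2, NA), n * m, replace = TRUE,
                         prob = c(0.3, 0.3, 0.3, 0.1)), n, m)
    # ensure each variant has an observed dosage and the score varies
    dos[1, ] <- ifelse(is.na(dos[1, ]), 1, dos[1, ])
    panel <- tiny_panel(dos, ref = rep("A", m), alt = rep("G", m))
    matched <- data.frame(snp = paste0("v", seq_len(m)),
                          beta = rnorm(m),
                          flipped = sample(c(TRUE, FALSE), m, TRUE),
                          stringsAsFactors = FALSE)
    got <- compute_scores(panel, matched)
    expect_equal(got$raw, oracle_score(dos, panel$variants, matched),
                 tolerance = 1e-12)
  }
})

test_that("score invariances hold: orientation, record order, null weights", {
  set.seed(32)
  dos <- matrix(sample(0:2, 8 * 6, replace = TRUE), 8, 6)
  panel <- tiny_panel(dos, ref = rep("A", 6), alt = rep("G", 6))
  w <- gwas_weights(paste0("v", 1:6),
                    effect_allele = rep("G", 6), other_allele = rep("A", 6),
                    beta = rnorm(6))
  base <- compute_scores(panel, match_variants(panel, w)$matched)

  # swapping alleles AND negating beta leaves raw scores unchanged up to
  # the constant 2*sum(beta): d*w vs (2-d)*(-w) = d*w - 2w  -> identical
  # standardized scores and identical raw differences between samples
  w_sw <- gwas_weights(w$snp, w$other_allele, w$effect_allele, -w$beta)
  sw <- compute_scores(panel, match_variants(panel, w_sw)$matched)
  expect_equal(diff(sw$raw), diff(base$raw), tolerance = 1e-12)
  expect_equal(sw$std, base$std, tolerance = 1e-12)

  # record order
  perm <- sample(6)
  w_perm <- gwas_weights(w$snp[perm], w$effect_allele[perm],
                         w$other_allele[perm], w$beta[perm])
  expect_equal(compute_scores(panel,
                              match_variants(panel, w_perm)$matched)$raw,
               base$raw, tolerance = 1e-12)

  # sample order
  perm_s <- sample(8)
  panel_p <- genotype_panel(dos[perm_s, ], panel$variants,
                            panel$sample_ids[perm_s])
  got_p <- compute_scores(panel_p, match_variants(panel_p, w)$matched)
  expect_equal(got_p$raw[order(perm_s)], base$raw, tolerance = 1e-12)

  # a zero-beta record changes nothing
  w_plus <- gwas_weights(c(w$snp, "v6b"), c(w$effect_allele, "G"),
                         c(w$other_allele, "A"), c(w$beta, 0))
  panel2 <- tiny_panel(cbind(dos, v6b = sample(0:2, 8, TRUE)),
                       ref = rep("A", 7), alt = rep("G", 7),
                       ids = c(paste0("v", 1:6), "v6b"))
  expect_equal(compute_scores(panel2,
                              match_variants(panel2, w_plus)$matched)$raw,
               base$raw, tolerance = 1e-12)
})

test_that("standardized scores meet the mean-0 / SD-1 contract", {
  sc <- small_cohort(seed = 33, n = 300, m = 50)
  m <- match_variants(sc$sim$panel, sc$sim$weights)
  s <- compute_scores(sc$sim$panel, m$matched)
  expect_lt(abs(mean(s$std)), 1e-8)
  expect_lt(abs(sd(s$std) - 1), 1e-8)
})

test_that("score_files wires reading, matching and scoring together", {
  sc <- small_cohort(seed = 34, n = 30, m = 20)
  dir <- withr::local_tempdir()
  paths <- write_fixture(sc$sim, sc$waves, dir)
  res <- score_files(paths[["vcf"]], paths[["weights"]])
  expect_equal(res$report$n_matched + res$report$n_ambiguous_removed, 20)
  direct <- compute_scores(sc$sim$panel,
                           match_variants(sc$sim$panel, sc$sim$weights)$matched)
  expect_equal(res$scores$raw, direct$raw, tolerance = 1e-12)
})
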