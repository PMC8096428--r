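fake_trend <- function(gene_id, z, q) {
  data.frame(feature_id = gene_id, estimate = z, se = 1, lrt = z^2,
             p = pmin(1, 2 * pnorm(-abs(z))), p_holm = NA, q_bh = q,
             z = z, fit_flag = "ok", stringsAsFactors = FALSE)
}

test_that("directional groups follow the z-score sign definitions", {
  m <- fake_trend(c("g1", "g2", "g3", "g4", "g5"),
                  c(3, -3, 3, -3, 2.5), c(0.01, 0.01, 0.01, 0.01, 0.01))
  p <- fake_trend(c("g1", "g2", "g3", "g4", "g5"),
                  c(4, 4, -4, -4, 1), c(0.01, 0.01, 0.01, 0.01, 0.5))
  rec <- classify_groups(m, p, q_threshold = 0.1)
  expect_equal(rec$group, c("A", "B", "C", "D", "NS"))
  expect_error(classify_groups(m, fake_trend("x1", 1, 0.01)), "shared")
})

test_that("doubly-significant genes partition into A-D and sign swap maps groups", {
  set.seed(20)
  ids <- sprintf("g%03d", 1:300)
  m <- fake_trend(ids, rnorm(300, 0, 2), runif(300, 0, 0.3))
  p <- fake_trend(ids, rnorm(300, 0, 2), runif(300, 0, 0.3))
  rec <- classify_groups(m, p, 0.1)
  both <- rec$sig_mrna & rec$sig_protein
  expect_equal(sum(rec$group != "NS"), sum(both))
  expect_true(all(table(rec$group[both]) >= 0))

  # flipping every protein z reverses the protein direction: A<->C, B<->D
  p_flip <- p
  p_flip$z <- -p_flip$z
  rec_flip <- classify_groups(m, p_flip, 0.1)
  map_p <- c(A = "C", B = "D", C = "A", D = "B", NS = "NS")
  expect_equal(rec_flip$group, unname(map_p[rec$group]))
  # flipping every mRNA z reverses the mRNA direction: A<->B, C<->D
  m_flip <- m
  m_flip$z <- -m_flip$z
  rec_flip_m <- classify_groups(m_flip, p, 0.1)
  map_m <- c(A = "B", B = "A", C = "D", D = "C", NS = "NS")
  expect_equal(rec_flip_m$group, unname(map_m[rec$group]))
})

test_that("group fractions reproduce the count arithmetic", {
  fr <- group_fractions(counts = c(A = 309, B = 196, C = 108, D = 359),
                        n_total = 6514)
  expect_equal(round(fr$pct_concordant, 1), 10.3)
  expect_equal(round(fr$pct_discordant, 1), 4.7)
  expect_equal(fr$n_significant, 972)

  fr_sex <- group_fractions(counts = c(A = 1545, B = 153, C = 610, D = 1391),
                            n_total = 6514)
  expect_equal(round(fr_sex$pct_discordant, 1), 11.7)

  all_ns <- data.frame(gene_id = c("a", "b"), z_mrna = c(1, -1),
                       z_protein = c(1, -1), sig_mrna = FALSE,
                       sig_protein = FALSE, group = "NS")
  fr0 <- group_fractions(all_ns)
  expect_equal(fr0$pct_concordant, 0)
  expect_equal(fr0$pct_discordant, 0)
})

test_that("z-score correlation handles identity, reversal, and subsets", {
  rec <- data.frame(gene_id = c("a", "b", "c"), z_mrna = c(1, 2, 3),
                    z_protein = c(1, 2, 3), sig_mrna = TRUE,
                    sig_protein = TRUE, group = "A")
  expect_equal(z_correlation(rec)$r, 1)
  rec$z_protein <- c(3, 2, 1)
  expect_equal(z_correlation(rec)$r, -1)
  rec$z_protein <- c(2, 2, 2)
  expect_error(z_correlation(rec), "constant")
  rec2 <- rbind(rec, rec)
  rec2$sig_mrna <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)
  expect_error(z_correlation(rec2[1:3, ], "doubly_significant"), "at least 3")
})

test_that("protein isoforms collapse to the smallest raw p per gene", {
  tab <- data.frame(feature_id = c("p1", "p2", "p3"),
                    gene_id = c("g1", "g1", "g2"),
                    p = c(0.05, 0.001, 0.2), z = c(1, 3, -1),
                    stringsAsFactors = FALSE)
  out <- collapse_proteins(tab)
  expect_equal(nrow(out), 2)
  expect_equal(out$feature_id[out$gene_id == "g1"], "p2")
})

test_that("sex trends are more concordant than age trends on default cohorts", {
  co <- simulate_cohort(cohort_sim_config(
    genes = c(concordant_up = 30, mrna_down_protein_up = 15,
              mrna_up_protein_down = 15, concordant_down = 30,
              mediated = 0, null = 60), seed = 21))
  md <- co$metadata
  sf <- median_ratio_size_factors(co$mrna)
  m_age <- nb_trend_test(co$mrna, md, model_spec("age_coded", c("sex", "batch")), sf)
  m_sex <- nb_trend_test(co$mrna, md, model_spec("sex", c("age_coded", "batch")), sf)
  p_age <- lmm_trend_test(co$protein, md,
                          model_spec("age_coded", "sex", c("tag", "generation")))
  p_sex <- lmm_trend_test(co$protein, md,
                          model_spec("sex", "age_coded", c("tag", "generation")))
  r_age <- z_correlation(classify_groups(m_age, p_age, 0.1))$r
  r_sex <- z_correlation(classify_groups(m_sex, p_sex, 0.1))$r
  # sex effects are transcriptionally driven, age effects only weakly coupled
  expect_gt(r_sex, r_age)
})
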