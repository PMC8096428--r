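meta6 <- function(n = 60) {
  data.frame(age_coded = rep(c(-0.5, 0, 0.5), each = n / 3),
             sex = factor(rep(c("M", "F"), n / 2)),
             batch = factor(rep(c("B1", "B2"), each = 2, length.out = n)),
             tag = factor(rep(1:6, length.out = n)),
             generation = factor(rep(1:3, length.out = n)))
}

test_that("NB trend test finds no signal in a flat row", {
  md <- meta6()
  r <- nb_trend_lrt(rep(25, 60), rep(1, 60), md,
                    model_spec("age_coded", c("sex", "batch")))
  expect_lt(r$lrt, 1e-6)
  expect_gt(r$p, 0.999)
  flat0 <- nb_trend_lrt(rep(0, 60), rep(1, 60), md,
                        model_spec("age_coded", c("sex", "batch")))
  expect_equal(flat0$fit_flag, "all_zero")
  expect_true(is.na(flat0$p))
})

test_that("NB LRT converges to an independent Poisson IRLS oracle as dispersion -> 0", {
  set.seed(10)
  md <- meta6()
  sf <- exp(rnorm(60, 0, 0.2))
  y <- rpois(60, 40 * sf * exp(0.4 * md$age_coded))
  spec <- model_spec("age_coded", c("sex", "batch"))
  r <- nb_trend_lrt(y, sf, md, spec, dispersion = 1e-8)

  X_full <- model.matrix(~ sex + batch + age_coded, md)
  X_red <- model.matrix(~ sex + batch, md)
  full <- poisson_irls(y, X_full, log(sf))
  red <- poisson_irls(y, X_red, log(sf))
  lrt_oracle <- 2 * (full$loglik - red$loglik)
  expect_equal(r$lrt, lrt_oracle, tolerance = 1e-4)
  expect_equal(r$estimate * log(2), unname(full$beta["age_coded"]),
               tolerance = 1e-4)
})

test_that("Holm and BH match hand-stepped values and dominance properties", {
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(holm_adjust(c(0.1, 1.2)), "0, 1")

  set.seed(11)
  for (i in 1:1000) {
    p <- runif(sample(2:20, 1))
    h <- holm_adjust(p)
    b <- bh_adjust(p)
    expect_true(all(h >= p))      # Holm dominates raw p
    expect_true(all(b <= h + 1e-12)) # BH q never exceeds Holm p
  }
})

test_that("trend contrast power matches the design calculation", {
  expect_equal(trend_power(64, 0.5, 0.05), 0.80, tolerance = 0.01)
  expect_equal(trend_power(64, 0, 0.05), 0.05, tolerance = 1e-12)
  pw <- sapply(c(16, 32, 64, 128), trend_power, effect_sd = 0.5, alpha = 0.05)
  expect_true(all(diff(pw) > 0))
  pw2 <- sapply(c(0.2, 0.4, 0.6), function(e) trend_power(64, e, 0.05))
  expect_true(all(diff(pw2) > 0))
  expect_error(trend_power(64, 0.5, 1.5), "alpha")
})

test_that("LMM with variance ratios forced to zero equals the OLS nested LRT", {
  set.seed(12)
  md <- meta6()
  y <- 0.3 * md$age_coded + (md$sex == "F") * 0.2 + rnorm(60)
  spec <- model_spec("age_coded", "sex", c("tag", "generation"))
  r <- lmm_trend_lrt(y, md, spec, gammas = c(0, 0))
  full <- lm(y ~ sex + age_coded, md)
  red <- lm(y ~ sex, md)
  lrt_ols <- 2 * (logLik(full) - logLik(red))
  expect_equal(r$lrt, as.numeric(lrt_ols), tolerance = 1e-6)
})

test_that("profiled LMM log-likelihood matches a dense grid+GLS oracle", {
  set.seed(13)
  n <- 24
  md <- data.frame(age_coded = rep(c(-0.5, 0, 0.5), each = 8),
                   sex = factor(rep(c("M", "F"), 12)),
                   grp = factor(rep(1:4, each = 6)))
  y <- 0.5 * md$age_coded + rnorm(4, 0, 0.6)[md$grp] + rnorm(n)
  X <- model.matrix(~ sex + age_coded, md)

  for (g in c(0.05, 0.3, 1, 4)) {
    mine <- fit_lmm_ml(y, X, list(md$grp), gammas = g)
    oracle <- dense_lmm_loglik(y, X, list(md$grp), g)
    expect_equal(mine$loglik, oracle, tolerance = 1e-4)
  }
  # the optimized fit cannot fall below the best grid point
  grid <- sapply(exp(seq(log(0.01), log(10), length.out = 60)),
                 function(g) dense_lmm_loglik(y, X, list(md$grp), g))
  opt <- fit_lmm_ml(y, X, list(md$grp))
  expect_gte(opt$loglik, max(grid) - 1e-4)
})

test_that("hand-rolled LMM agrees with lme4 maximum likelihood", {
  skip_if_not_installed("lme4")
  set.seed(14)
  md <- meta6(96)
  y <- 0.4 * md$age_coded + 0.3 * (md$sex == "F") +
    rnorm(6, 0, 0.4)[md$tag] + rnorm(3, 0, 0.3)[md$generation] + rnorm(96)
  X <- model.matrix(~ sex + age_coded, md)
  mine <- fit_lmm_ml(y, X, list(md$tag, md$generation))
  ref <- suppressMessages(lme4::lmer(
    y ~ sex + age_coded + (1 | tag) + (1 | generation), md, REML = FALSE))
  expect_equal(mine$loglik, as.numeric(logLik(ref)), tolerance = 1e-5)
  expect_equal(unname(mine$beta), unname(lme4::fixef(ref)), tolerance = 1e-4)
})

test_that("full-model log-likelihood dominates the reduced model per feature", {
  co <- simulate_cohort(small_cohort_config(seed = 15))
  md <- co$metadata
  spec <- model_spec("age_coded", "sex", c("tag", "generation"))
  for (g in c(1, 25, 50)) {
    y <- rank_normal_transform(co$protein[g, ])
    r <- lmm_trend_lrt(y, md, spec)
    expect_gte(r$lrt, 0)
  }
})

test_that("sex as focal term reuses the trend machinery", {
  set.seed(16)
  md <- meta6()
  sf <- rep(1, 60)
  y <- rnbinom(60, mu = 50 * exp(1 * (md$sex == "F")), size = 10)
  r_sex <- nb_trend_lrt(y, sf, md, model_spec("sex", c("age_coded", "batch")))
  expect_lt(r_sex$p, 1e-4)
  y2 <- 0.8 * (md$sex == "F") + rnorm(60, 0, 0.5)
  r_lmm <- lmm_trend_lrt(rank_normal_transform(y2), md,
                         model_spec("sex", "age_coded", c("tag", "generation")))
  expect_lt(r_lmm$p, 1e-4)
})

test_that("singular fixed designs are rejected with the aliased column named", {
  md <- meta6()
  md$dup <- as.numeric(md$age_coded)
  X <- model.matrix(~ age_coded + dup, md)
  expect_error(fit_lmm_ml(rnorm(60), X, list(md$tag)), "aliased.*dup")
})

test_that("result tables carry adjusted p-values over converged fits only", {
  co <- simulate_cohort(small_cohort_config(seed = 17))
  counts <- co$mrna[1:12, ]
  counts[3, ] <- 0
  tab <- nb_trend_test(counts, co$metadata,
                       model_spec("age_coded", c("sex", "batch")))
  expect_equal(tab$fit_flag[3], "all_zero")
  expect_true(is.na(tab$p_holm[3]))
  ok <- tab$fit_flag == "ok"
  expect_equal(tab$p_holm[ok], holm_adjust(tab$p[ok]))
  expect_equal(tab$q_bh[ok], bh_adjust(tab$p[ok]))
  expect_true(all(tab$p_holm[ok] >= tab$p[ok]))
  expect_true(all(tab$q_bh[ok] <= tab$p_holm[ok] + 1e-12))
  expect_equal(tab$z[ok], tab$estimate[ok] / tab$se[ok])
})
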