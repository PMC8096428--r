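test_that("PCA fractions match an independent eigen decomposition", {
  set.seed(40)
  m <- matrix(rnorm(30 * 12), 30, 12,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:12)))
  pc <- pca_variance(m, 3)
  ev <- eigen(cov(scale(t(m), scale = FALSE)), symmetric = TRUE)$values
  expect_equal(pc$variance_fraction[1:12],
               (ev / sum(ev))[1:12], tolerance = 1e-8)
  expect_true(all(diff(pc$variance_fraction) < 1e-12))
  expect_lte(sum(pc$variance_fraction), 1 + 1e-8)
  expect_error(pca_variance(m, 13), "exceeds")
})

test_that("a rank-1 matrix loads entirely on PC1 and reordering is sign-invariant", {
  v <- rnorm(10)
  m <- outer(rep(1, 8), v) * c(1, 2, 1.5, 0.5, 3, 1, 2, 1)
  rownames(m) <- paste0("g", 1:8)
  pc <- pca_variance(m, 2)
  expect_equal(pc$variance_fraction[1], 1, tolerance = 1e-12)

  set.seed(41)
  m2 <- matrix(rnorm(80), 8, 10, dimnames = list(paste0("g", 1:8), NULL))
  a <- pca_variance(m2, 2)
  b <- pca_variance(m2[sample(8), ], 2)
  expect_equal(abs(a$scores), abs(b$scores), tolerance = 1e-8)
  expect_equal(a$variance_fraction, b$variance_fraction, tolerance = 1e-10)
})

test_that("PC-covariate association separates signal from noise", {
  co <- simulate_cohort(small_cohort_config(seed = 42))
  md <- co$metadata
  sex_score <- as.numeric(md$sex == "F")
  expect_lt(suppressWarnings(pc_association(sex_score, factor(md$sex))), 1e-15)
  expect_lt(suppressWarnings(pc_association(md$age_coded, md$age_coded)), 1e-15)
  expect_gt(pc_association(md$age_coded, factor(md$sex)), 0.01)
  expect_error(pc_association(rnorm(10), rep(1, 10)), "constant")

  set.seed(43)
  p_null <- replicate(500, pc_association(rnorm(188), md$age_coded))
  expect_gt(ks.test(p_null, "punif")$p.value, 0.01)
})

test_that("marker selection respects the cap and drops indistinguishable types", {
  ref <- simulate_reference_profiles(3, 500, 80, seed = 44)
  mk <- select_markers(ref$profiles, max_markers = 50)
  expect_true(all(lengths(mk) <= 50))

  twin <- cbind(typeX = c(10, 1, 1, 5), typeY = c(10, 1, 1, 5))
  rownames(twin) <- paste0("g", 1:4)
  expect_warning(mk2 <- select_markers(twin), "dropped")
  expect_equal(length(mk2), 0)
  expect_error(select_markers(twin[, 1, drop = FALSE]), "2 cell types")
})

test_that("SPV of two identical markers equals their standardized profile", {
  set.seed(45)
  prof <- rnorm(20)
  bulk <- rbind(m1 = prof, m2 = prof, other = rnorm(20))
  colnames(bulk) <- paste0("s", 1:20)
  r <- compute_spv(bulk, c("m1", "m2"), "t")
  expect_equal(unname(r$spv), as.numeric(scale(prof)), tolerance = 1e-8)
  expect_error(compute_spv(bulk, "m1"), "fewer than 2")
})

test_that("permuting samples permutes the SPV identically", {
  set.seed(46)
  bulk <- matrix(rexp(300), 15, 20,
                 dimnames = list(paste0("g", 1:15), paste0("s", 1:20)))
  mk <- paste0("g", 1:5)
  r1 <- compute_spv(bulk, mk)
  perm <- sample(20)
  r2 <- compute_spv(bulk[, perm], mk)
  expect_equal(unname(r2$spv), unname(r1$spv[perm]), tolerance = 1e-10)
})

test_that("SPVs track true mixing proportions and detect an age trend", {
  set.seed(47)
  co <- simulate_cohort(small_cohort_config(seed = 47))
  md <- co$metadata
  n <- nrow(md)
  ref <- simulate_reference_profiles(3, 300, 15, seed = 48)
  # B-cell-like type1 proportion increases with age; others fill the rest
  p1 <- plogis(-1.4 + 1.2 * md$age_coded + rnorm(n, 0, 0.2))
  rest <- 1 - p1
  p2 <- rest * 0.6
  p3 <- rest * 0.4
  props <- rbind(p1, p2, p3)
  bulk <- ref$profiles %*% props * exp(matrix(rnorm(300 * n, 0, 0.1), 300, n))
  colnames(bulk) <- md$sample_id
  mk <- select_markers(ref$profiles)
  tab <- spv_table(upper_quartile_normalize(bulk), mk, md)
  spv1 <- as.numeric(tab[tab$cell_type == "type1",
                         -(1:4)])
  expect_gt(abs(cor(spv1, p1)), 0.9)
  expect_lt(tab$trend_p[tab$cell_type == "type1"], 0.05)
})

test_that("constant true proportions yield no spurious age trend", {
  set.seed(49)
  co <- simulate_cohort(small_cohort_config(seed = 49))
  md <- co$metadata
  n <- nrow(md)
  ref <- simulate_reference_profiles(2, 150, 10, seed = 50)
  rejections <- replicate(60, {
    p1 <- plogis(qlogis(0.3) + rnorm(n, 0, 0.3))
    props <- rbind(p1, 1 - p1)
    bulk <- ref$profiles %*% props *
      exp(matrix(rnorm(150 * n, 0, 0.1), 150, n))
    colnames(bulk) <- md$sample_id
    r <- compute_spv(upper_quartile_normalize(bulk),
                     select_markers(ref$profiles)$type1, "type1", md)
    r$trend_p < 0.05
  })
  expect_lte(mean(rejections), 0.15)
})

test_that("hypergeometric tail equals exact enumeration on small universes", {
  # closed-form check of the printed example
  expect_equal(ora_hypergeometric(paste0("g", 1:4), paste0("g", 1:5),
                                  paste0("g", 1:10))$p,
               choose(5, 4) * choose(5, 0) / choose(10, 4),
               tolerance = 1e-12)

  enumerate_tail <- function(N, K, k, obs) {
    # P(X >= obs) by summing the counting formula over all overlaps
    sum(sapply(obs:min(K, k), function(x)
      choose(K, x) * choose(N - K, k - x))) / choose(N, k)
  }
  set.seed(51)
  for (i in 1:50) {
    N <- sample(4:12, 1)
    uni <- paste0("g", seq_len(N))
    K <- sample(1:N, 1)
    k <- sample(1:N, 1)
    cat_set <- sample(uni, K)
    sel <- sample(uni, k)
    got <- ora_hypergeometric(sel, cat_set, uni)
    expect_equal(got$p, enumerate_tail(N, K, k, got$overlap),
                 tolerance = 1e-12)
  }
  uni <- paste0("g", 1:8)
  expect_equal(ora_hypergeometric(uni[1:3], uni, uni)$p, 1)
  expect_equal(ora_hypergeometric(uni[1:2], character(0), uni)$p, 1)
  expect_error(ora_hypergeometric("a", "a", character(0)), "universe")
})
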