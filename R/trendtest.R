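#' Model specification for per-feature trend tests
#'
#' Describes the focal term (the coefficient tested by the likelihood-ratio
#' test), the fixed covariates, and any random-intercept factors. The trend
#' test compares the full model (covariates + focal) against the reduced
#' model (covariates only); random structure, when present, is shared by both.
#'
#' @param focal Name of the focal column in the metadata (e.g. `"age_coded"`
#'   or `"sex"`).
#' @param covariates Character vector of fixed-covariate column names.
#' @param random Character vector of random-intercept factor column names
#'   (used by [lmm_trend_lrt()] only).
#' @return An object of class `"model_spec"`.
#' @export
model_spec <- function(focal, covariates = character(), random = character()) {
  stopifnot(is.character(focal), length(focal) == 1)
  if (focal %in% covariates)
    stop("focal term `", focal, "` must not also appear in `covariates`")
  structure(list(focal = focal, covariates = covariates, random = random),
            class = "model_spec")
}

trend_result_row <- function(estimate = NA_real_, se = NA_real_,
                             lrt = NA_real_, p = NA_real_,
                             fit_flag = "ok") {
  z <- if (is.finite(se) && se > 0) estimate / se else NA_real_
  data.frame(estimate = estimate, se = se, lrt = lrt, p = p, z = z,
             fit_flag = fit_flag, stringsAsFactors = FALSE)
}

nb_loglik <- function(y, mu, theta) sum(stats::dnbinom(y, size = theta, mu = mu, log = TRUE))

#' Negative binomial likelihood-ratio trend test for one count row
#'
#' Fits a negative binomial log-link GLM with a log size-factor offset under
#' the full (covariates + focal) and reduced (covariates only) models, using a
#' single gene-wise dispersion estimated by maximum likelihood under the full
#' model and shared by both fits, and reports the 1-df likelihood-ratio
#' statistic for the focal term. The slope and its standard error are
#' converted to log2 units; when age is coded (-0.5, 0, 0.5) across groups
#' spanning one year, the estimate reads as log2 fold change per year.
#'
#' @param counts_row Non-negative integer vector of counts, one per sample.
#' @param size_factors Positive per-sample normalization factors.
#' @param data Data frame of per-sample covariates (columns named in `spec`).
#' @param spec A [model_spec()]; `random` is ignored here.
#' @param dispersion Optional fixed NB dispersion (1/theta). `NULL` (default)
#'   estimates it by ML under the full model.
#' @return One-row data frame: `estimate`, `se`, `lrt`, `p`, `z`, `fit_flag`.
#'   Non-convergent or all-zero rows are flagged with `NA` statistics rather
#'   than raising an error.
#' @export
nb_trend_lrt <- function(counts_row, size_factors, data, spec,
                         dispersion = NULL) {
  y <- as.numeric(counts_row)
  n <- length(y)
  if (length(size_factors) != n || nrow(data) != n)
    stop("counts, size factors, and metadata must cover the same samples")
  if (any(size_factors <= 0)) stop("size factors must be positive")
  if (all(y == 0)) return(trend_result_row(fit_flag = "all_zero"))

  rhs_red <- if (length(spec$covariates))
    paste(spec$covariates, collapse = " + ") else "1"
  f_full <- stats::as.formula(paste("y ~", rhs_red, "+", spec$focal))
  f_red <- stats::as.formula(paste("y ~", rhs_red))
  df <- data
  df$y <- y
  off <- log(size_factors)

  fit <- tryCatch({
    if (is.null(dispersion)) {
      # ML dispersion under the full model; data without overdispersion push
      # theta to infinity, where the NB fit degenerates to Poisson
      theta <- tryCatch(suppressWarnings(
        MASS::glm.nb(stats::update(f_full, . ~ . + offset(off)),
                     data = df)$theta),
        error = function(e) 1e8)
      theta <- min(max(theta, 1e-8), 1e8)
    } else {
      if (dispersion <= 0) stop("dispersion must be positive")
      theta <- 1 / dispersion
    }
    fam <- MASS::negative.binomial(theta = theta)
    full <- suppressWarnings(stats::glm(f_full, family = fam, data = df, offset = off))
    red <- suppressWarnings(stats::glm(f_red, family = fam, data = df, offset = off))
    ll_full <- nb_loglik(y, stats::fitted(full), theta)
    ll_red <- nb_loglik(y, stats::fitted(red), theta)
    lrt <- max(0, 2 * (ll_full - ll_red))
    cf <- summary(full)$coefficients
    focal_name <- grep(spec$focal, rownames(cf), value = TRUE, fixed = TRUE)[1]
    est <- cf[focal_name, "Estimate"] / log(2)
    se <- cf[focal_name, "Std. Error"] / log(2)
    trend_result_row(est, se, lrt, stats::pchisq(lrt, 1, lower.tail = FALSE))
  }, error = function(e) trend_result_row(fit_flag = "non_convergent"))
  fit
}

## ---- random-intercept linear mixed model, profiled ML ----

lmm_precompute <- function(y, X, Z_list) {
  Z <- if (length(Z_list)) do.call(cbind, Z_list) else matrix(0, length(y), 0)
  block <- rep(seq_along(Z_list), vapply(Z_list, ncol, 0L))
  list(n = length(y), p = ncol(X), XtX = crossprod(X), Xty = crossprod(X, y),
       yty = sum(y * y), XtZ = crossprod(X, Z), Zty = crossprod(Z, y),
       ZtZ = crossprod(Z), block = block, k = length(Z_list))
}

# Profiled ML log-likelihood of y ~ N(X beta, sigma2 * (I + sum_k g_k Z_k Z_k'))
# with beta and sigma2 profiled out; Woodbury keeps everything q x q.
lmm_profile_eval <- function(gamma, pc) {
  active <- which(gamma > 1e-10)
  use <- pc$block %in% active
  if (any(use)) {
    g <- gamma[pc$block[use]]
    A <- diag(1 / g, sum(use)) + pc$ZtZ[use, use, drop = FALSE]
    cA <- chol(A)
    Ai_Zty <- backsolve(cA, forwardsolve(t(cA), pc$Zty[use, , drop = FALSE]))
    Ai_ZtX <- backsolve(cA, forwardsolve(t(cA), t(pc$XtZ[, use, drop = FALSE])))
    XtWiX <- pc$XtX - pc$XtZ[, use, drop = FALSE] %*% Ai_ZtX
    XtWiy <- pc$Xty - pc$XtZ[, use, drop = FALSE] %*% Ai_Zty
    yWiy <- pc$yty - sum(pc$Zty[use, ] * Ai_Zty)
    logdetW <- 2 * sum(log(diag(cA))) + sum(log(g))
  } else {
    XtWiX <- pc$XtX; XtWiy <- pc$Xty; yWiy <- pc$yty; logdetW <- 0
  }
  cX <- tryCatch(chol(XtWiX), error = function(e) NULL)
  if (is.null(cX)) return(list(loglik = -Inf))
  beta <- backsolve(cX, forwardsolve(t(cX), XtWiy))
  rss <- max(yWiy - sum(beta * XtWiy), 1e-12)
  sigma2 <- rss / pc$n
  loglik <- -0.5 * pc$n * (log(2 * pi * sigma2) + 1) - 0.5 * logdetW
  cov_beta <- sigma2 * chol2inv(cX)
  list(loglik = as.numeric(loglik), beta = drop(beta), sigma2 = sigma2,
       cov_beta = cov_beta)
}

#' Fit a random-intercept linear mixed model by maximum likelihood
#'
#' Direct optimization of the profiled log-likelihood over the
#' variance-component ratios `gamma_k = var_k / sigma2` (one per random
#' factor), with the fixed effects and residual variance profiled out in
#' closed form (GLS). `gammas` can be fixed to evaluate a constrained fit,
#' e.g. `c(0, 0)` for the ordinary-least-squares limit.
#'
#' @param y Numeric response vector.
#' @param X Fixed-effect design matrix (with intercept column).
#' @param random_factors List of factors (each a per-sample factor with >= 2
#'   levels) receiving independent random intercepts.
#' @param gammas Optional fixed non-negative variance ratios; `NULL` estimates
#'   them.
#' @return List with `loglik`, `beta`, `cov_beta`, `sigma2`, `gammas`, and
#'   `boundary` (TRUE if any estimated ratio hit 0).
#' @export
fit_lmm_ml <- function(y, X, random_factors = list(), gammas = NULL) {
  X <- as.matrix(X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("singular fixed-effect design; aliased columns: ",
         paste(bad, collapse = ", "))
  }
  Z_list <- lapply(random_factors, function(f) {
    f <- droplevels(as.factor(f))
    if (nlevels(f) < 2) stop("each random factor needs at least 2 levels")
    stats::model.matrix(~ 0 + f)
  })
  pc <- lmm_precompute(y, X, Z_list)
  k <- pc$k
  if (k == 0 || !is.null(gammas)) {
    g <- if (k == 0) numeric(0) else {
      if (length(gammas) != k) stop("`gammas` must have one value per random factor")
      if (any(gammas < 0)) stop("variance ratios must be non-negative")
      gammas
    }
    fit <- lmm_profile_eval(g, pc)
    return(c(fit, list(gammas = g, boundary = any(g <= 1e-10) && k > 0)))
  }
  obj <- function(g) -lmm_profile_eval(g, pc)$loglik
  opt <- stats::optim(rep(0.1, k), obj, method = "L-BFGS-B",
                      lower = rep(0, k), upper = rep(1e4, k))
  # the boundary (all ratios 0) is a valid ML solution L-BFGS-B can miss
  ll0 <- obj(rep(0, k))
  g_hat <- if (ll0 < opt$value) rep(0, k) else opt$par
  fit <- lmm_profile_eval(g_hat, pc)
  c(fit, list(gammas = g_hat, boundary = any(g_hat <= 1e-10)))
}

#' Linear mixed model likelihood-ratio trend test for one abundance row
#'
#' Tests the focal fixed effect by comparing full and reduced random-intercept
#' models, both fitted by maximum likelihood (ML, not REML, so the
#' log-likelihoods are comparable across fixed-effect structures) with the
#' random structure shared. Intended for rank-normal transformed protein
#' abundances with e.g. MS labeling tag and cohort generation as random
#' factors and sex as a fixed covariate.
#'
#' @param abundance_row Numeric vector (already rank-normal transformed).
#' @param data Data frame of per-sample covariates and random factors.
#' @param spec A [model_spec()] naming focal, covariates, and random factors.
#' @param gammas Optional fixed variance ratios passed to [fit_lmm_ml()].
#' @return One-row data frame: `estimate`, `se`, `lrt`, `p`, `z`, `fit_flag`
#'   (`"boundary"` when a variance component is estimated at 0).
#' @export
lmm_trend_lrt <- function(abundance_row, data, spec, gammas = NULL) {
  y <- as.numeric(abundance_row)
  if (nrow(data) != length(y))
    stop("abundance row and metadata must cover the same samples")
  rhs_red <- if (length(spec$covariates))
    paste(spec$covariates, collapse = " + ") else "1"
  X_full <- stats::model.matrix(
    stats::as.formula(paste("~", rhs_red, "+", spec$focal)), data)
  X_red <- stats::model.matrix(stats::as.formula(paste("~", rhs_red)), data)
  rf <- lapply(spec$random, function(nm) data[[nm]])

  full <- fit_lmm_ml(y, X_full, rf, gammas = gammas)
  red <- fit_lmm_ml(y, X_red, rf, gammas = gammas)
  if (!is.finite(full$loglik) || !is.finite(red$loglik))
    return(trend_result_row(fit_flag = "non_convergent"))
  lrt <- max(0, 2 * (full$loglik - red$loglik))
  focal_idx <- grep(spec$focal, colnames(X_full), fixed = TRUE)[1]
  est <- full$beta[focal_idx]
  se <- sqrt(full$cov_beta[focal_idx, focal_idx])
  flag <- if (isTRUE(full$boundary) || isTRUE(red$boundary)) "boundary" else "ok"
  out <- trend_result_row(est, se, lrt,
                          stats::pchisq(lrt, 1, lower.tail = FALSE))
  out$fit_flag <- flag
  out
}

## ---- multiple testing ----

check_pvec <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  p
}

#' Holm step-down family-wise error adjustment
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (monotone, capped at 1), same order as input.
#' @export
holm_adjust <- function(p) stats::p.adjust(check_pvec(p), method = "holm")

#' Benjamini-Hochberg step-up false discovery rate adjustment
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return BH q-values (monotone, capped at 1), same order as input.
#' @export
bh_adjust <- function(p) stats::p.adjust(check_pvec(p), method = "BH")

#' Power of the linear age-trend contrast
#'
#' Two-sided normal-approximation power for a linear contrast across equally
#' spaced age groups with coded values spanning (-0.5, ..., 0.5), e.g.
#' (-0.5, 0, 0.5) for three groups. `effect_sd` is the difference in means
#' between the first and last groups in units of within-group standard
#' deviation; the noncentrality is `effect_sd * sum(c^2) / sqrt(sum(c^2)/n)`.
#'
#' @param n_per_group Animals per age group (>= 2).
#' @param effect_sd Trend size: first-to-last group mean difference in SD units.
#' @param alpha Two-sided unadjusted type I error rate in (0, 1).
#' @param n_groups Number of equally spaced age groups (default 3).
#' @return Power in `[0, 1]`.
#' @examples
#' trend_power(64, 0.5, 0.05) # ~0.80
#' @export
trend_power <- function(n_per_group, effect_sd, alpha, n_groups = 3) {
  if (n_per_group < 2) stop("`n_per_group` must be at least 2")
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)")
  cc <- seq(-0.5, 0.5, length.out = n_groups)
  ncp <- effect_sd * sum(cc^2) / sqrt(sum(cc^2) / n_per_group)
  zcrit <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(ncp - zcrit) + stats::pnorm(-ncp - zcrit)
}

## ---- matrix-level drivers ----

finalize_trend_table <- function(tab) {
  ok <- tab$fit_flag %in% c("ok", "boundary")
  tab$p_holm <- NA_real_
  tab$q_bh <- NA_real_
  if (any(ok)) {
    tab$p_holm[ok] <- holm_adjust(tab$p[ok])
    tab$q_bh[ok] <- bh_adjust(tab$p[ok])
  }
  tab[, c("feature_id", "estimate", "se", "lrt", "p", "p_holm", "q_bh",
          "z", "fit_flag")]
}

#' Count-matrix trend test (NB GLM per gene)
#'
#' Applies [nb_trend_lrt()] to every row of a count matrix and assembles the
#' per-feature result table with Holm and Benjamini-Hochberg adjustments
#' computed over the converged fits.
#'
#' @param counts Count matrix, genes in rows, samples in columns.
#' @param data Per-sample covariate data frame, rows aligned to columns of
#'   `counts`.
#' @param spec A [model_spec()].
#' @param size_factors Optional; computed by [median_ratio_size_factors()]
#'   when `NULL`.
#' @param dispersion Optional fixed dispersion passed through.
#' @return Data frame with columns `feature_id`, `estimate`, `se`, `lrt`,
#'   `p`, `p_holm`, `q_bh`, `z`, `fit_flag`.
#' @export
nb_trend_test <- function(counts, data, spec, size_factors = NULL,
                          dispersion = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("feature", seq_len(nrow(counts)))
  if (is.null(size_factors)) size_factors <- median_ratio_size_factors(counts)
  rows <- lapply(seq_len(nrow(counts)), function(i)
    nb_trend_lrt(counts[i, ], size_factors, data, spec, dispersion))
  tab <- do.call(rbind, rows)
  tab <- cbind(feature_id = rownames(counts), tab, stringsAsFactors = FALSE)
  finalize_trend_table(tab)
}

#' Abundance-matrix trend test (random-intercept LMM per protein)
#'
#' Rank-normal transforms each row (unless `transform = FALSE`) and applies
#' [lmm_trend_lrt()], assembling the adjusted result table.
#'
#' @param abundances Numeric matrix, proteins in rows, samples in columns.
#' @param data Per-sample covariate/random-factor data frame.
#' @param spec A [model_spec()] with `random` factors.
#' @param transform Apply [rank_normal_transform()] per row first
#'   (default TRUE).
#' @return Data frame in the same layout as [nb_trend_test()].
#' @export
lmm_trend_test <- function(abundances, data, spec, transform = TRUE) {
  abundances <- as.matrix(abundances)
  if (is.null(rownames(abundances)))
    rownames(abundances) <- paste0("feature", seq_len(nrow(abundances)))
  rows <- lapply(seq_len(nrow(abundances)), function(i) {
    y <- abundances[i, ]
    if (transform) y <- rank_normal_transform(y)
    lmm_trend_lrt(y, data, spec)
  })
  tab <- do.call(rbind, rows)
  tab <- cbind(feature_id = rownames(abundances), tab, stringsAsFactors = FALSE)
  finalize_trend_table(tab)
}
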