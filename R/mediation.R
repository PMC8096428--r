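gaussian_lrt_p <- function(rss0, rss1, n, df = 1) {
  # chi-square LRT for nested Gaussian linear models: n * log(RSS0/RSS1)
  if (rss1 < 1e-12 && rss0 < 1e-12) return(1)
  lrt <- max(0, n * log(rss0 / max(rss1, 1e-300)))
  stats::pchisq(lrt, df, lower.tail = FALSE)
}

rss_of <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

#' Transcriptome-wide mediation scan
#'
#' For each gene measured on both platforms, compares the significance of the
#' focal term (age trend or sex) on protein between two ordinary
#' least-squares models: `Protein ~ Age + Sex + Generation` (base) and
#' `Protein ~ mRNA + Age + Sex + Generation` (adjusted). A drop in
#' significance when mRNA enters the model — a positive `delta` on the
#' -log10 p scale — indicates transcriptional mediation of the focal effect.
#'
#' @param protein,mrna Feature x sample matrices, rank-normal transformed per
#'   row, with gene IDs as row names; samples aligned to `metadata` rows.
#' @param metadata Data frame with `age_coded`, `sex`, `generation`.
#' @param focal `"age_coded"` or `"sex"`; the other remains a covariate.
#' @return Data frame `gene_id`, `focal`, `neglog10_p_base`,
#'   `neglog10_p_adj`, `delta`, `fit_flag`.
#' @export
mediation_scan <- function(protein, mrna, metadata,
                           focal = c("age_coded", "sex")) {
  focal <- match.arg(focal)
  shared <- intersect(rownames(protein), rownames(mrna))
  if (!length(shared)) stop("no genes shared between protein and mRNA matrices")
  if (ncol(protein) != nrow(metadata) || ncol(mrna) != nrow(metadata))
    stop("matrices and metadata must cover the same samples")
  n <- nrow(metadata)
  X <- stats::model.matrix(~ age_coded + sex + generation, metadata)
  focal_col <- grep(focal, colnames(X), fixed = TRUE)
  X0 <- X[, -focal_col, drop = FALSE]

  rows <- lapply(shared, function(g) {
    y <- protein[g, ]
    m <- mrna[g, ]
    Xa <- cbind(X, mrna = m)
    Xa0 <- cbind(X0, mrna = m)
    if (qr(Xa)$rank < ncol(Xa)) {
      return(data.frame(gene_id = g, focal = focal,
                        neglog10_p_base = NA_real_, neglog10_p_adj = NA_real_,
                        delta = NA_real_, fit_flag = "rank_deficient",
                        stringsAsFactors = FALSE))
    }
    p_base <- gaussian_lrt_p(rss_of(X0, y), rss_of(X, y), n)
    p_adj <- gaussian_lrt_p(rss_of(Xa0, y), rss_of(Xa, y), n)
    b <- -log10(max(p_base, 1e-300))
    a <- -log10(max(p_adj, 1e-300))
    data.frame(gene_id = g, focal = focal, neglog10_p_base = b,
               neglog10_p_adj = a, delta = b - a, fit_flag = "ok",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

major_axis_slope <- function(x, y) {
  v <- stats::var(cbind(x, y))
  if (sum(diag(v)) < 1e-24) return(1)
  e <- eigen(v, symmetric = TRUE)$vectors[, 1]
  if (abs(e[1]) < 1e-12) return(Inf)
  # orient so the slope of the identity-like axis is positive when cov >= 0
  e[2] / e[1]
}

#' Summarize a mediation scan
#'
#' @param records Output of [mediation_scan()].
#' @param delta0 Threshold on `delta` for the exceedance fraction
#'   (default 0.5, about a 3-fold drop in the focal p-value).
#' @return List: `median_delta`, `frac_exceeding`, `major_axis_slope` (of the
#'   base vs adjusted -log10 p cloud; near 1 with points on the identity
#'   line), `n`.
#' @export
mediation_summary <- function(records, delta0 = 0.5) {
  records <- records[records$fit_flag == "ok" & is.finite(records$delta), ]
  if (nrow(records) < 10) stop("need at least 10 converged mediation records")
  list(median_delta = stats::median(records$delta),
       frac_exceeding = mean(records$delta > delta0),
       major_axis_slope = major_axis_slope(records$neglog10_p_base,
                                           records$neglog10_p_adj),
       n = nrow(records))
}

#' Partial correlation given covariates
#'
#' Pearson correlation of the least-squares residuals of `x` and `y` on the
#' covariate design (an intercept is always included), with a t-test p-value
#' on `n - rank - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors.
#' @param covariates Matrix or data frame of covariates (may be NULL for the
#'   marginal correlation).
#' @return List `r`, `p`, `df`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stop("`x` and `y` must have equal length")
  C <- cbind(`(Intercept)` = rep(1, n),
             if (!is.null(covariates)) as.matrix(covariates))
  r_rank <- qr(C)$rank
  if (r_rank < ncol(C)) stop("rank-deficient covariate matrix")
  if (n <= r_rank + 2) stop("too few observations for the covariate set")
  rx <- stats::lm.fit(C, x)$residuals
  ry <- stats::lm.fit(C, y)$residuals
  # a variable fully explained by the covariates has no residual variation
  # left to correlate: report 0 rather than noise at machine precision
  if (sum(rx^2) < 1e-18 * max(1, sum(x^2)) ||
      sum(ry^2) < 1e-18 * max(1, sum(y^2)))
    return(list(r = 0, p = 1, df = n - r_rank - 2))
  r <- stats::cor(rx, ry)
  df <- n - r_rank - 2
  tt <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tt), df), df = df)
}

#' Urinary phenotype mediation test
#'
#' Reports the age-term p-value from `Phenotype ~ Age + Sex` and from
#' `Phenotype ~ Protein + Age + Sex`, plus the sex-adjusted partial
#' correlation of the phenotype with the protein. Mediation is consistent
#' with a small first p-value and a larger second one; both are reported and
#' no dichotomous verdict is forced.
#'
#' @param phenotype Numeric vector (already creatinine-adjusted, see
#'   [adjust_urine_analyte()]).
#' @param protein_row Protein abundance vector aligned to samples.
#' @param metadata Data frame with `age_coded` and `sex`.
#' @param phenotype_name,protein_id Optional labels carried into the result.
#' @return List: `phenotype`, `protein_id`, `partial_r`, `partial_r_p`,
#'   `p_age_base`, `p_age_adjusted`.
#' @export
phenotype_mediation_test <- function(phenotype, protein_row, metadata,
                                     phenotype_name = "phenotype",
                                     protein_id = "protein") {
  n <- nrow(metadata)
  if (length(phenotype) != n || length(protein_row) != n)
    stop("phenotype, protein, and metadata must cover the same samples")
  X <- stats::model.matrix(~ age_coded + sex, metadata)
  age_col <- grep("age_coded", colnames(X), fixed = TRUE)
  X0 <- X[, -age_col, drop = FALSE]
  constant_protein <- stats::sd(protein_row) == 0
  Xa <- if (constant_protein) X else cbind(X, protein = protein_row)
  Xa0 <- if (constant_protein) X0 else cbind(X0, protein = protein_row)
  sex_ind <- stats::model.matrix(~ sex, metadata)[, -1, drop = FALSE]
  pc <- if (constant_protein) list(r = NA_real_, p = NA_real_) else
    partial_correlation(phenotype, protein_row, sex_ind)
  list(phenotype = phenotype_name, protein_id = protein_id,
       partial_r = pc$r, partial_r_p = pc$p,
       p_age_base = gaussian_lrt_p(rss_of(X0, phenotype),
                                   rss_of(X, phenotype), n),
       p_age_adjusted = gaussian_lrt_p(rss_of(Xa0, phenotype),
                                       rss_of(Xa, phenotype), n))
}
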