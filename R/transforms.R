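#' Rank-based inverse normal transformation
#'
#' Maps a numeric vector to normal scores through its (mid-)ranks:
#' `qnorm((r - offset) / (n - 2*offset + 1))`. Ties receive equal scores via
#' mid-ranks. With the default `offset = 0.5` the middle observation of an
#' odd-length tie-free vector maps exactly to 0; `offset = 0.375` gives Blom
#' scores.
#'
#' @param x Numeric vector, length at least 3, not all values identical.
#' @param offset Rank offset in `[0, 0.5]`.
#' @return Numeric vector of normal scores, same length and order as `x`.
#' @examples
#' rank_normal_transform(c(10, 20, 30))
#' @export
rank_normal_transform <- function(x, offset = 0.5) {
  if (!is.numeric(x)) stop("`x` must be numeric")
  n <- length(x)
  if (n < 3) stop("rank-normal transform needs at least 3 observations")
  if (anyNA(x)) stop("`x` contains missing values")
  if (!is.numeric(offset) || length(offset) != 1 || offset < 0 || offset > 0.5)
    stop("`offset` must be a single value in [0, 0.5]")
  if (diff(range(x)) == 0)
    stop("all values identical: no ordering information for rank-normal scores")
  r <- rank(x, ties.method = "average")
  stats::qnorm((r - offset) / (n - 2 * offset + 1))
}

#' Median-of-ratios size factors
#'
#' Per-sample scaling factors for a count matrix, computed as the median over
#' reference genes (genes with nonzero counts in every sample) of the ratio of
#' each sample's count to the gene's geometric mean, then rescaled so the
#' factors have geometric mean 1.
#'
#' @param counts Non-negative count matrix, genes in rows, samples in columns.
#' @return Positive numeric vector of length `ncol(counts)`, named by sample.
#' @export
median_ratio_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref))
    stop("no gene has nonzero counts in all samples; filter low-count genes first")
  logc <- log(counts[ref, , drop = FALSE])
  loggeo <- rowMeans(logc)
  factors <- apply(logc, 2, function(col) exp(stats::median(col - loggeo)))
  factors <- factors / exp(mean(log(factors)))
  stats::setNames(factors, colnames(counts))
}

#' Shifted-log variance stabilization
#'
#' Normalizes counts by size factors and applies `log2(x + pseudocount)`.
#' A light-weight stabilization for PCA-style analyses; the transform
#' descriptor records the pseudocount.
#'
#' @param counts Count matrix, genes in rows.
#' @param size_factors Positive per-sample factors (see
#'   [median_ratio_size_factors()]).
#' @param pseudocount Positive shift added before the log (default 1).
#' @return A matrix of the same shape with attribute `transform` describing
#'   the method and pseudocount.
#' @export
variance_stabilize <- function(counts, size_factors, pseudocount = 1) {
  counts <- as.matrix(counts)
  if (length(size_factors) != ncol(counts))
    stop("`size_factors` length must equal the number of samples")
  if (any(size_factors <= 0)) stop("size factors must be positive")
  out <- log2(sweep(counts, 2, size_factors, "/") + pseudocount)
  attr(out, "transform") <- list(method = "shifted_log2", pseudocount = pseudocount)
  out
}

#' Creatinine adjustment of a urinary analyte
#'
#' Adjusts a urinary analyte for urine concentration using creatinine, either
#' as the log ratio (`method = "ratio"`) or as the residuals of log analyte
#' regressed on log creatinine (`method = "residual"`, the default).
#' Below-detection values can be floored before the log.
#'
#' @param analyte Positive numeric vector.
#' @param creatinine Positive numeric vector, same length.
#' @param method `"residual"` or `"ratio"`.
#' @param floor Optional positive value substituted for analyte values at or
#'   below it (e.g. half a detection threshold); `NULL` means no flooring and
#'   non-positive values are an error.
#' @return Numeric adjusted vector.
#' @export
adjust_urine_analyte <- function(analyte, creatinine,
                                 method = c("residual", "ratio"),
                                 floor = NULL) {
  method <- match.arg(method)
  if (length(analyte) != length(creatinine))
    stop("`analyte` and `creatinine` must have equal length")
  if (any(creatinine <= 0)) stop("creatinine values must be positive")
  if (!is.null(floor)) {
    if (floor <= 0) stop("`floor` must be positive")
    analyte <- pmax(analyte, floor)
  }
  if (any(analyte <= 0))
    stop("non-positive analyte value; supply `floor` to handle below-detection values")
  if (method == "ratio") {
    log(analyte / creatinine)
  } else {
    stats::resid(stats::lm(log(analyte) ~ log(creatinine)))
  }
}

#' Upper-quartile normalization of a count matrix
#'
#' Scales each sample so that its upper quartile of nonzero counts equals the
#' geometric mean of those quartiles across samples. Used ahead of
#' marker-based deconvolution to remove library-size differences.
#'
#' @param counts Count matrix, genes in rows.
#' @return Matrix of normalized values, same shape.
#' @export
upper_quartile_normalize <- function(counts) {
  counts <- as.matrix(counts)
  uq <- apply(counts, 2, function(col) {
    nz <- col[col > 0]
    if (!length(nz)) stop("a sample has all-zero counts")
    stats::quantile(nz, 0.75, names = FALSE)
  })
  target <- exp(mean(log(uq)))
  sweep(counts, 2, uq / target, "/")
}
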