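#' Principal-component variance partitioning
#'
#' PCA of the sample x feature matrix after per-feature centering (no
#' scaling; rank-normal input is already on a common scale). Variance
#' fractions come from the squared singular values; score signs are fixed so
#' that the feature with the largest absolute loading on each component has a
#' positive loading.
#'
#' @param mat Feature x sample numeric matrix (rank-normal transformed per
#'   feature is recommended).
#' @param k Number of components to keep (`<= min(dim)`).
#' @return List: `variance_fraction` (all components), `scores`
#'   (sample x k), `loadings` (feature x k).
#' @export
pca_variance <- function(mat, k) {
  mat <- as.matrix(mat)
  if (k > min(dim(mat))) stop("`k` exceeds the matrix rank bound")
  pr <- stats::prcomp(t(mat), center = TRUE, scale. = FALSE)
  frac <- pr$sdev^2 / sum(pr$sdev^2)
  scores <- pr$x[, seq_len(k), drop = FALSE]
  loadings <- pr$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    top <- which.max(abs(loadings[, j]))
    if (loadings[top, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(variance_fraction = frac, scores = scores, loadings = loadings)
}

#' Association of a principal component with a covariate
#'
#' F-test p-value from the linear model `score ~ covariate`; a numeric
#' covariate (e.g. coded age) enters as a linear term, a factor (e.g. sex) as
#' a categorical effect.
#'
#' @param scores Per-sample component scores.
#' @param covariate Numeric or factor covariate, same length.
#' @return P-value of the covariate effect.
#' @export
pc_association <- function(scores, covariate) {
  if (length(unique(covariate)) < 2) stop("constant covariate")
  fit <- stats::lm(scores ~ covariate)
  av <- stats::anova(fit)
  av[["Pr(>F)"]][1]
}

#' Select cell-type marker genes from reference profiles
#'
#' For each cell type, candidate markers are genes whose highest mean
#' expression is in that type; they are ranked by the ratio of the highest to
#' the second-highest type mean, genes with ratio below `min_ratio` are
#' dropped, and at most `max_markers` are kept per type.
#'
#' @param reference Gene x cell-type matrix of non-negative mean profiles.
#' @param max_markers Marker cap per type (default 50).
#' @param min_ratio Minimum first-to-second ratio (default 2).
#' @return Named list (one element per retained type) of marker gene IDs;
#'   types with no qualifying marker are dropped with a warning.
#' @export
select_markers <- function(reference, max_markers = 50, min_ratio = 2) {
  reference <- as.matrix(reference)
  if (ncol(reference) < 2) stop("need at least 2 cell types")
  if (any(reference < 0)) stop("reference profiles must be non-negative")
  eps <- 1e-9
  top_type <- apply(reference, 1, which.max)
  sorted2 <- apply(reference, 1, function(r) sort(r, decreasing = TRUE)[1:2])
  ratio <- (sorted2[1, ] + eps) / (sorted2[2, ] + eps)
  out <- lapply(seq_len(ncol(reference)), function(t) {
    cand <- which(top_type == t & ratio >= min_ratio)
    cand <- cand[order(ratio[cand], decreasing = TRUE)]
    rownames(reference)[utils::head(cand, max_markers)]
  })
  names(out) <- colnames(reference)
  empty <- lengths(out) == 0
  if (any(empty)) {
    warning("no qualifying markers for: ",
            paste(names(out)[empty], collapse = ", "), "; type(s) dropped")
    out <- out[!empty]
  }
  out
}

#' Surrogate proportion variable for one cell type
#'
#' The "raw" surrogate proportion variable: the first principal component of
#' the per-marker standardized marker x sample submatrix, extracted without
#' any covariate adjustment so that age trends in the SPV are estimated
#' independently of the age model. The component is sign-oriented to
#' correlate positively with the mean standardized marker signal and
#' standardized to mean 0, SD 1. When metadata are supplied the SPV's age
#' trend is tested with `SPV ~ age_coded + sex`.
#'
#' @param bulk Gene x sample expression matrix (upper-quartile normalized
#'   counts, see [upper_quartile_normalize()], or other normalized values).
#' @param markers Character vector of marker gene IDs for the type (>= 2 must
#'   be present in `bulk`).
#' @param cell_type Label carried into the result.
#' @param metadata Optional data frame with `age_coded` and `sex` for the
#'   trend test.
#' @return List: `cell_type`, `markers` (those used), `spv` (named per-sample
#'   vector), `trend_p` (or `NA` without metadata).
#' @export
compute_spv <- function(bulk, markers, cell_type = "type", metadata = NULL) {
  present <- intersect(markers, rownames(bulk))
  if (length(present) < 2)
    stop("fewer than 2 markers of ", cell_type, " present in the bulk matrix")
  sub <- bulk[present, , drop = FALSE]
  std <- t(apply(sub, 1, function(r) {
    s <- stats::sd(r)
    if (s == 0) rep(0, length(r)) else (r - mean(r)) / s
  }))
  sv <- svd(std)
  spv <- sv$v[, 1]
  if (stats::cor(spv, colMeans(std)) < 0) spv <- -spv
  spv <- as.numeric(scale(spv))
  names(spv) <- colnames(bulk)
  trend_p <- NA_real_
  if (!is.null(metadata)) {
    fit <- stats::lm(spv ~ age_coded + sex, data = metadata)
    trend_p <- stats::anova(fit)[["Pr(>F)"]][1]
  }
  list(cell_type = cell_type, markers = present, spv = spv, trend_p = trend_p)
}

#' Surrogate proportion variables for all cell types
#'
#' Runs [compute_spv()] per type and adjusts the age-trend p-values across
#' types with Benjamini-Hochberg.
#'
#' @param bulk Gene x sample matrix.
#' @param marker_map Named list of marker vectors (see [select_markers()]).
#' @param metadata Data frame with `age_coded` and `sex`.
#' @return Data frame with `cell_type`, `n_markers`, `trend_p`, `trend_q`,
#'   then one column per sample.
#' @export
spv_table <- function(bulk, marker_map, metadata) {
  res <- lapply(names(marker_map), function(ct)
    compute_spv(bulk, marker_map[[ct]], ct, metadata))
  tab <- data.frame(cell_type = vapply(res, `[[`, "", "cell_type"),
                    n_markers = vapply(res, function(r) length(r$markers), 0L),
                    trend_p = vapply(res, `[[`, 0, "trend_p"),
                    stringsAsFactors = FALSE)
  tab$trend_q <- bh_adjust(tab$trend_p)
  cbind(tab, do.call(rbind, lapply(res, function(r) as.data.frame(t(r$spv)))))
}

#' Hypergeometric over-representation test
#'
#' One-sided tail probability that a selected gene set overlaps a category at
#' least as much as observed, under hypergeometric sampling from the
#' universe. BH adjustment across categories is left to the caller.
#'
#' @param selected,category,universe Character vectors of gene IDs; both
#'   `selected` and `category` must be subsets of `universe`.
#' @return List `overlap`, `p`.
#' @export
ora_hypergeometric <- function(selected, category, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  selected <- unique(selected)
  category <- unique(category)
  if (!all(selected %in% universe) || !all(category %in% universe))
    stop("`selected` and `category` must be subsets of `universe`")
  overlap <- length(intersect(selected, category))
  p <- stats::phyper(overlap - 1, length(category),
                     length(universe) - length(category), length(selected),
                     lower.tail = FALSE)
  list(overlap = overlap, p = p)
}
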