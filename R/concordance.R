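#' Collapse multiple proteins per gene to one
#'
#' When the protein table carries several isoforms per gene, keeps the row
#' with the smallest raw p-value (ties broken by feature ID for
#' reproducibility).
#'
#' @param protein Trend-result table with a `gene_id` column (or `feature_id`
#'   used as the gene ID when absent).
#' @return The table with one row per gene.
#' @export
collapse_proteins <- function(protein) {
  if (is.null(protein$gene_id)) protein$gene_id <- protein$feature_id
  ord <- order(protein$gene_id, protein$p, protein$feature_id)
  protein <- protein[ord, ]
  protein[!duplicated(protein$gene_id), ]
}

#' Classify genes into directional concordance groups
#'
#' Joins mRNA and protein trend results on gene ID, flags significance on each
#' platform at a BH q threshold, and assigns each doubly-significant gene to
#' one of four directional groups by the signs of its z-scores:
#' A (both up), B (mRNA down, protein up), C (mRNA up, protein down),
#' D (both down); all other genes are `NS`.
#'
#' @param mrna,protein Trend-result tables (see [nb_trend_test()]); `protein`
#'   should already be one row per gene (see [collapse_proteins()]).
#' @param q_threshold BH q significance cutoff on each platform (default 0.1).
#' @return Data frame `gene_id`, `z_mrna`, `z_protein`, `sig_mrna`,
#'   `sig_protein`, `group`.
#' @export
classify_groups <- function(mrna, protein, q_threshold = 0.1) {
  gid_m <- if (is.null(mrna$gene_id)) mrna$feature_id else mrna$gene_id
  gid_p <- if (is.null(protein$gene_id)) protein$feature_id else protein$gene_id
  shared <- intersect(gid_m, gid_p)
  if (!length(shared)) stop("no genes shared between the mRNA and protein tables")
  im <- match(shared, gid_m)
  ip <- match(shared, gid_p)
  rec <- data.frame(
    gene_id = shared,
    z_mrna = mrna$z[im], z_protein = protein$z[ip],
    sig_mrna = !is.na(mrna$q_bh[im]) & mrna$q_bh[im] < q_threshold,
    sig_protein = !is.na(protein$q_bh[ip]) & protein$q_bh[ip] < q_threshold,
    stringsAsFactors = FALSE)
  both <- rec$sig_mrna & rec$sig_protein
  if (any(both & (rec$z_mrna == 0 | rec$z_protein == 0), na.rm = TRUE))
    stop("significant gene with z-score exactly 0: contradictory input")
  grp <- rep("NS", nrow(rec))
  grp[both & rec$z_mrna > 0 & rec$z_protein > 0] <- "A"
  grp[both & rec$z_mrna < 0 & rec$z_protein > 0] <- "B"
  grp[both & rec$z_mrna > 0 & rec$z_protein < 0] <- "C"
  grp[both & rec$z_mrna < 0 & rec$z_protein < 0] <- "D"
  rec$group <- grp
  rec
}

#' Concordance group counts and fractions
#'
#' Summarizes a concordance table (or raw group counts) into per-group counts
#' and the percentage of all shared genes with concordant (A + D) and
#' discordant (B + C) significant changes.
#'
#' @param records Output of [classify_groups()], or `NULL` if `counts` given.
#' @param counts Optional named counts `c(A=, B=, C=, D=)` with `n_total`.
#' @param n_total Total shared genes (required with `counts`).
#' @return List: `counts` (named A/B/C/D/NS), `n_total`, `n_significant`,
#'   `pct_concordant`, `pct_discordant`.
#' @export
group_fractions <- function(records = NULL, counts = NULL, n_total = NULL) {
  if (is.null(counts)) {
    if (!nrow(records)) stop("`records` is empty")
    counts <- c(A = sum(records$group == "A"), B = sum(records$group == "B"),
                C = sum(records$group == "C"), D = sum(records$group == "D"))
    n_total <- nrow(records)
  } else {
    if (is.null(n_total)) stop("`n_total` is required with explicit counts")
    counts <- counts[c("A", "B", "C", "D")]
  }
  n_sig <- sum(counts)
  list(counts = c(counts, NS = n_total - n_sig),
       n_total = n_total, n_significant = n_sig,
       pct_concordant = 100 * (counts[["A"]] + counts[["D"]]) / n_total,
       pct_discordant = 100 * (counts[["B"]] + counts[["C"]]) / n_total)
}

#' Correlation of mRNA and protein trend z-scores
#'
#' Pearson correlation between the per-gene mRNA and protein z-scores, over
#' all shared genes or only the doubly-significant subset.
#'
#' @param records Output of [classify_groups()].
#' @param subset `"all"` or `"doubly_significant"`.
#' @return List `r`, `p`, `n`.
#' @export
z_correlation <- function(records, subset = c("all", "doubly_significant")) {
  subset <- match.arg(subset)
  if (subset == "doubly_significant")
    records <- records[records$sig_mrna & records$sig_protein, ]
  records <- records[is.finite(records$z_mrna) & is.finite(records$z_protein), ]
  if (nrow(records) < 3) stop("need at least 3 genes in the subset")
  if (stats::sd(records$z_mrna) == 0 || stats::sd(records$z_protein) == 0)
    stop("constant z-score vector: correlation undefined")
  ct <- stats::cor.test(records$z_mrna, records$z_protein)
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(records))
}
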