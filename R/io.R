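delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a delimited expression table
#'
#' Reads a feature x sample table (one header row of sample IDs, one leading
#' column of feature IDs) from TSV or CSV (delimiter chosen by extension).
#' Duplicate feature or sample IDs and non-numeric cells are errors with the
#' offending coordinates named; missing cells are kept as `NA` and counted in
#' the `n_missing` attribute, never silently zeroed.
#'
#' @param path File path (`.tsv`/`.txt` tab-delimited, `.csv`
#'   comma-delimited).
#' @param rows_are_features If `FALSE` the table is transposed after reading.
#' @return Numeric matrix, features in rows.
#' @export
read_expression_table <- function(path, rows_are_features = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, sep = delim_for(path), header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           quote = "\"", comment.char = "")
  ids <- raw[[1]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate feature IDs: ", paste(dup, collapse = ", "))
  samples <- colnames(raw)[-1]
  dup_s <- unique(samples[duplicated(samples)])
  if (length(dup_s))
    stop("duplicate sample IDs: ", paste(dup_s, collapse = ", "))
  cells <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(cells), dim(cells)))
  bad <- which(is.na(num) & !(is.na(cells) | cells %in% c("", "NA")),
               arr.ind = TRUE)
  if (nrow(bad))
    stop("non-numeric cell at feature '", ids[bad[1, 1]], "', sample '",
         samples[bad[1, 2]], "': ", cells[bad[1, 1], bad[1, 2]])
  mat <- matrix(num, nrow(cells), ncol(cells),
                dimnames = list(ids, samples))
  if (!rows_are_features) mat <- t(mat)
  attr(mat, "n_missing") <- sum(is.na(mat))
  mat
}

#' Write an expression table
#'
#' Writes a feature x sample matrix as delimited text (delimiter by
#' extension) with full `%.17g` precision so that numeric values round-trip
#' bit-exactly through [read_expression_table()].
#'
#' @param mat Numeric matrix with row and column names.
#' @param path Output path (`.tsv` or `.csv`).
#' @param id_column Header for the leading feature-ID column.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(mat, path, id_column = "feature_id") {
  cells <- matrix(sprintf("%.17g", mat), nrow(mat), ncol(mat))
  cells[is.na(mat)] <- "NA"
  out <- cbind(rownames(mat), cells)
  colnames(out) <- c(id_column, colnames(mat))
  utils::write.table(out, path, sep = delim_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Holds input paths, significance thresholds, age coding, the rank-normal
#' offset, the seed, and the output directory. When all input paths are
#' `NULL`, [run_pipeline()] simulates a cohort instead of reading files.
#'
#' @param mrna,protein,metadata,phenotype,reference Optional input table
#'   paths.
#' @param alpha Family-wise significance level in (0, 1) (default 0.05).
#' @param fdr_q FDR threshold in (0, 1) (default 0.1).
#' @param age_coding Strictly increasing coded age values
#'   (default `c(-0.5, 0, 0.5)`).
#' @param rank_offset Rank-normal offset in `[0, 0.5]`.
#' @param seed Non-negative integer seed.
#' @param out_dir Output directory for result tables and the run log.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(mrna = NULL, protein = NULL, metadata = NULL,
                            phenotype = NULL, reference = NULL,
                            alpha = 0.05, fdr_q = 0.1,
                            age_coding = c(-0.5, 0, 0.5), rank_offset = 0.5,
                            seed = 1L, out_dir = tempfile("agetrends_run_")) {
  if (alpha <= 0 || alpha >= 1 || fdr_q <= 0 || fdr_q >= 1)
    stop("significance thresholds must lie in (0, 1)")
  if (any(diff(age_coding) <= 0))
    stop("age coding values must be strictly increasing")
  if (seed < 0 || seed != round(seed))
    stop("`seed` must be a non-negative integer")
  structure(list(mrna = mrna, protein = protein, metadata = metadata,
                 phenotype = phenotype, reference = reference, alpha = alpha,
                 fdr_q = fdr_q, age_coding = age_coding,
                 rank_offset = rank_offset, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Comma-separated
#' values become vectors; numeric-looking values are converted. Keys match
#' the arguments of [pipeline_config()].
#'
#' @param path Config file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  vals <- lapply(kv, function(x) {
    v <- strsplit(x[2], "\\s*,\\s*")[[1]]
    num <- suppressWarnings(as.numeric(v))
    if (!anyNA(num)) num else v
  })
  names(vals) <- vapply(kv, `[[`, "", 1)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

read_metadata_table <- function(path) {
  md <- utils::read.table(path, sep = delim_for(path), header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "age_coded", "sex")
  miss <- setdiff(need, colnames(md))
  if (length(miss)) stop("metadata lacks columns: ", paste(miss, collapse = ", "))
  for (col in intersect(c("generation", "batch", "tag", "sex"), colnames(md)))
    md[[col]] <- factor(md[[col]])
  rownames(md) <- md$sample_id
  md
}

write_result_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full joint mRNA-protein aging pipeline
#'
#' Orchestrates the analysis end to end: size-factor normalization and NB
#' trend tests for counts, rank-normal transformation and LMM trend tests for
#' protein, concordance classification, age and sex mediation scans, PCA
#' variance partitioning with covariate association, surrogate-proportion
#' deconvolution (when a reference is available), and urinary-phenotype
#' mediation (when phenotypes are available). Writes each result as a
#' tab-delimited table under `config$out_dir` plus a run log recording the
#' seed, thresholds, and sample/feature counts at every stage.
#'
#' With no input paths configured, a synthetic cohort (plus reference
#' profiles and urine phenotypes) is simulated from `cohort_config`, so the
#' whole pipeline is exercisable without external data.
#'
#' @param config A [pipeline_config()].
#' @param cohort_config A [cohort_sim_config()] used when simulating; its
#'   seed is overridden by `config$seed`.
#' @return Invisibly, a named list of the result tables and the output paths.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         cohort_config = cohort_sim_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("agetrends run: seed=%d alpha=%g fdr_q=%g rank_offset=%g",
                         config$seed, config$alpha, config$fdr_q,
                         config$rank_offset),
                 sprintf("age coding: %s",
                         paste(config$age_coding, collapse = ", ")))
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))

  simulated <- is.null(config$mrna) && is.null(config$protein)
  if (simulated) {
    cohort_config$seed <- config$seed
    cohort <- simulate_cohort(cohort_config)
    mrna <- cohort$mrna; protein <- cohort$protein; metadata <- cohort$metadata
    ref <- simulate_reference_profiles(3, nrow(mrna), 10,
                                       seed = config$seed + 1)
    # plant the reference markers in the bulk matrix gene universe
    reference <- ref$profiles
    say("simulated cohort: %d genes x %d samples", nrow(mrna), ncol(mrna))
  } else {
    if (is.null(config$mrna) || is.null(config$protein) ||
        is.null(config$metadata))
      stop("mrna, protein, and metadata paths are all required")
    mrna <- read_expression_table(config$mrna)
    protein <- read_expression_table(config$protein)
    metadata <- read_metadata_table(config$metadata)
    reference <- if (!is.null(config$reference))
      read_expression_table(config$reference) else NULL
    say("read inputs: %d mRNA x %d samples, %d proteins",
        nrow(mrna), ncol(mrna), nrow(protein))
  }

  shared_samples <- Reduce(intersect, list(colnames(mrna), colnames(protein),
                                           rownames(metadata)))
  if (!length(shared_samples))
    stop("no samples shared between expression matrices and metadata")
  mrna <- mrna[, shared_samples, drop = FALSE]
  protein <- protein[, shared_samples, drop = FALSE]
  metadata <- metadata[shared_samples, , drop = FALSE]
  say("aligned samples: %d", length(shared_samples))

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  sf <- run_stage("size_factors", median_ratio_size_factors(mrna))
  mrna_spec <- model_spec("age_coded",
                          intersect(c("sex", "batch"), colnames(metadata)))
  mrna_trends <- run_stage("mrna_trends",
                           nb_trend_test(mrna, metadata, mrna_spec, sf))
  say("mRNA trend tests: %d features, %d flagged", nrow(mrna_trends),
      sum(mrna_trends$fit_flag != "ok"))

  prot_spec <- model_spec("age_coded", "sex",
                          intersect(c("tag", "generation"), colnames(metadata)))
  protein_trends <- run_stage("protein_trends",
                              lmm_trend_test(protein, metadata, prot_spec))
  say("protein trend tests: %d features", nrow(protein_trends))

  protein_collapsed <- collapse_proteins(protein_trends)
  concord <- run_stage("concordance",
                       classify_groups(mrna_trends, protein_collapsed,
                                       config$fdr_q))
  fr <- group_fractions(concord)
  say("concordance: %d shared genes, %d doubly significant, %.1f%% concordant, %.1f%% discordant",
      fr$n_total, fr$n_significant, fr$pct_concordant, fr$pct_discordant)

  rn <- function(m) t(apply(m, 1, rank_normal_transform,
                            offset = config$rank_offset))
  vst <- variance_stabilize(mrna, sf)
  mrna_rn <- run_stage("rank_normal", rn(vst))
  protein_rn <- rn(protein)

  med_age <- run_stage("mediation_age",
                       mediation_scan(protein_rn, mrna_rn, metadata, "age_coded"))
  med_sex <- run_stage("mediation_sex",
                       mediation_scan(protein_rn, mrna_rn, metadata, "sex"))
  say("mediation scans: %d genes (age), %d genes (sex)",
      nrow(med_age), nrow(med_sex))

  pca_summary <- run_stage("pca", {
    do.call(rbind, lapply(list(mrna = mrna_rn, protein = protein_rn),
                          function(m) {
      pc <- pca_variance(m, 4)
      data.frame(pc = 1:4,
                 variance_fraction = pc$variance_fraction[1:4],
                 p_age = vapply(1:4, function(j)
                   pc_association(pc$scores[, j], metadata$age_coded), 0),
                 p_sex = vapply(1:4, function(j)
                   pc_association(pc$scores[, j], factor(metadata$sex)), 0))
    })) -> tab
    tab$platform <- rep(c("mrna", "protein"), each = 4)
    tab[, c("platform", "pc", "variance_fraction", "p_age", "p_sex")]
  })
  say("PCA: top-4 variance %.1f%% (mRNA), %.1f%% (protein)",
      100 * sum(pca_summary$variance_fraction[1:4]),
      100 * sum(pca_summary$variance_fraction[5:8]))

  spv <- NULL
  if (!is.null(reference)) {
    spv <- run_stage("spv", {
      markers <- select_markers(reference)
      spv_table(upper_quartile_normalize(mrna), markers, metadata)
    })
    say("SPV: %d cell types", nrow(spv))
  }

  phen_summary <- NULL
  phen <- if (simulated) {
    top <- protein_trends$feature_id[which.min(protein_trends$p)]
    simulate_urine(metadata, protein[top, ], effect = 0.5,
                   seed = config$seed + 2)
  } else if (!is.null(config$phenotype)) {
    utils::read.table(config$phenotype, sep = delim_for(config$phenotype),
                      header = TRUE, stringsAsFactors = FALSE)
  }
  if (!is.null(phen)) {
    phen_summary <- run_stage("phenotype_mediation", {
      phen <- phen[match(rownames(metadata), phen$sample_id), ]
      top <- protein_trends$feature_id[which.min(protein_trends$p)]
      do.call(rbind, lapply(c("phosphate", "albumin"), function(an) {
        adj <- adjust_urine_analyte(phen[[an]], phen$creatinine,
                                    method = "residual", floor = 0.5)
        as.data.frame(phenotype_mediation_test(adj, protein_rn[top, ],
                                               metadata, an, top))
      }))
    })
    say("phenotype mediation: protein %s", phen_summary$protein_id[1])
  }

  tables <- list(mrna_trends = mrna_trends, protein_trends = protein_trends,
                 concordance = concord, mediation_age = med_age,
                 mediation_sex = med_sex, pca_summary = pca_summary,
                 spv = spv, phenotype_mediation = phen_summary)
  tables <- tables[!vapply(tables, is.null, TRUE)]
  paths <- vapply(names(tables), function(nm)
    write_result_table(tables[[nm]], file.path(config$out_dir,
                                               paste0(nm, ".tsv"))), "")
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  invisible(c(tables, list(paths = paths, log = log_lines)))
}
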