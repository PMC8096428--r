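#' Configuration for the synthetic cohort generator
#'
#' Defines a cross-sectional two-platform cohort: three age groups (6, 12, 18
#' months) by two sexes with per-cell sample sizes defaulting to the 188-mouse
#' kidney design (30/31/34 males and 33/31/29 females), and a gene panel split
#' into classes by their true age behaviour:
#' \describe{
#'   \item{concordant_up / concordant_down}{mRNA and protein both trend up
#'     (down) with age, via independent mRNA and direct protein effects.}
#'   \item{mrna_down_protein_up / mrna_up_protein_down}{discordant directions.}
#'   \item{mediated}{the protein age trend is carried entirely by the latent
#'     mRNA signal (direct protein age effect 0, coupling `lambda != 0`).}
#'   \item{null}{no age effect on either platform.}
#' }
#' Sex effects are transcriptionally driven for every gene: a gene-level sex
#' effect enters the latent mRNA signal and reaches protein only through the
#' coupling `lambda`.
#'
#' @param n_male,n_female Samples per age group (length 3, ages 6/12/18).
#' @param genes Named integer vector of class sizes; names must be
#'   `concordant_up`, `mrna_down_protein_up`, `mrna_up_protein_down`,
#'   `concordant_down`, `mediated`, `null`.
#' @param mrna_age_range Magnitude range (natural-log scale per year) for
#'   mRNA age slopes of the concordant/discordant classes; kept modest so
#'   that transcript trends are of the order seen in bulk aging tissue.
#' @param mediated_mrna_age_range Magnitude range for mRNA age slopes of the
#'   mediated class, larger so the transcriptional trend is strong enough to
#'   drive a detectable protein trend through `lambda`.
#' @param protein_age_range Magnitude range (protein-scale units per coded-age
#'   unit) for direct protein age effects.
#' @param sex_sd SD of gene-level sex effects on the latent mRNA signal.
#' @param batch_sd SD of gene-level RNA-batch effects (2 batches).
#' @param tag_sd,generation_sd SDs of protein random intercepts for the MS tag
#'   (16 levels) and cohort generation (5 levels).
#' @param dispersion_range NB dispersion range, sampled per gene.
#' @param lambda Latent mRNA to protein coupling coefficient.
#' @param bio_sd SD of the per-sample latent biological signal shared by the
#'   two platforms.
#' @param protein_noise_sd Protein measurement noise SD.
#' @param libsize_sd SD of log-normal library-size offsets.
#' @param baseline_log_range Range of baseline log mean expression.
#' @param seed Non-negative integer random seed.
#' @return A validated list of class `"cohort_sim_config"`.
#' @export
cohort_sim_config <- function(n_male = c(30, 31, 34),
                              n_female = c(33, 31, 29),
                              genes = c(concordant_up = 200,
                                        mrna_down_protein_up = 100,
                                        mrna_up_protein_down = 100,
                                        concordant_down = 200,
                                        mediated = 200,
                                        null = 1200),
                              mrna_age_range = c(0.1, 0.4),
                              mediated_mrna_age_range = c(0.5, 1.0),
                              protein_age_range = c(0.2, 0.5),
                              sex_sd = 1.0,
                              batch_sd = 0.2,
                              tag_sd = 0.3,
                              generation_sd = 0.2,
                              dispersion_range = c(0.05, 0.2),
                              lambda = 0.5,
                              bio_sd = 0.4,
                              protein_noise_sd = 0.7,
                              libsize_sd = 0.3,
                              baseline_log_range = log(c(50, 2000)),
                              seed = 1L) {
  classes <- c("concordant_up", "mrna_down_protein_up", "mrna_up_protein_down",
               "concordant_down", "mediated", "null")
  if (!setequal(names(genes), classes))
    stop("`genes` must be named with exactly: ", paste(classes, collapse = ", "))
  genes <- genes[classes]
  if (any(genes < 0) || sum(genes) == 0)
    stop("gene class counts must be non-negative and total at least 1")
  if (length(n_male) != 3 || length(n_female) != 3)
    stop("`n_male` and `n_female` must give counts for ages 6, 12, 18 months")
  if (any(c(n_male, n_female) < 2))
    stop("every (age, sex) cell needs n >= 2; models are unidentifiable otherwise")
  if (any(dispersion_range <= 0)) stop("dispersions must be positive")
  if (seed < 0 || seed != round(seed)) stop("`seed` must be a non-negative integer")
  structure(list(n_male = n_male, n_female = n_female, genes = genes,
                 mrna_age_range = mrna_age_range,
                 mediated_mrna_age_range = mediated_mrna_age_range,
                 protein_age_range = protein_age_range,
                 sex_sd = sex_sd, batch_sd = batch_sd, tag_sd = tag_sd,
                 generation_sd = generation_sd,
                 dispersion_range = dispersion_range, lambda = lambda,
                 bio_sd = bio_sd, protein_noise_sd = protein_noise_sd,
                 libsize_sd = libsize_sd,
                 baseline_log_range = baseline_log_range,
                 seed = as.integer(seed)),
            class = "cohort_sim_config")
}

runif_range <- function(n, range) stats::runif(n, range[1], range[2])

#' Simulate a paired mRNA/protein aging cohort
#'
#' Generates an NB count matrix, a continuous protein abundance matrix, a
#' sample metadata table, and a per-gene truth table under the generative
#' model of [cohort_sim_config()]: counts are drawn negative binomial with
#' log-mean `baseline + age_coded * slope + latent + batch + log library
#' offset`; protein is `lambda * latent + direct_age * age_coded + tag +
#' generation + noise`, where the latent signal carries the biological
#' deviation, the sex effect, and (for mediated genes only) the mRNA age
#' trend. The latent input to protein is the NB log-mean signal, not the
#' sampled count, so count noise attenuates but does not destroy within-age
#' mRNA-protein correlation.
#'
#' @param config A [cohort_sim_config()].
#' @return List with elements `mrna` (counts), `protein`, `metadata`
#'   (columns `sample_id`, `age_months`, `age_coded`, `sex`, `generation`,
#'   `batch`, `tag`), and `truth` (gene class, true slopes, mediation flag,
#'   sex effects).
#' @export
simulate_cohort <- function(config = cohort_sim_config()) {
  stopifnot(inherits(config, "cohort_sim_config"))
  set.seed(config$seed)
  ages <- c(6, 12, 18)
  meta <- do.call(rbind, lapply(1:3, function(a) {
    rbind(data.frame(age_months = ages[a], sex = "M", n = config$n_male[a]),
          data.frame(age_months = ages[a], sex = "F", n = config$n_female[a]))
  }))
  metadata <- meta[rep(seq_len(nrow(meta)), meta$n), c("age_months", "sex")]
  n <- nrow(metadata)
  metadata$sample_id <- sprintf("S%03d", seq_len(n))
  metadata$age_coded <- (metadata$age_months - 12) / 12
  metadata$generation <- factor(sample(paste0("G", 8:12), n, replace = TRUE))
  metadata$batch <- factor(sample(c("B1", "B2"), n, replace = TRUE))
  metadata$tag <- factor(sample(sprintf("T%02d", 1:16), n, replace = TRUE))
  rownames(metadata) <- metadata$sample_id
  metadata <- metadata[, c("sample_id", "age_months", "age_coded", "sex",
                           "generation", "batch", "tag")]

  g_counts <- config$genes
  G <- sum(g_counts)
  class_vec <- rep(names(g_counts), g_counts)
  gene_id <- sprintf("gene%04d", seq_len(G))

  sgn_m <- c(concordant_up = 1, mrna_down_protein_up = -1,
             mrna_up_protein_down = 1, concordant_down = -1,
             mediated = NA, null = 0)[class_vec]
  sgn_m[class_vec == "mediated"] <- sample(c(-1, 1), sum(class_vec == "mediated"),
                                           replace = TRUE)
  sgn_p <- c(concordant_up = 1, mrna_down_protein_up = 1,
             mrna_up_protein_down = -1, concordant_down = -1,
             mediated = 0, null = 0)[class_vec]

  b_m <- sgn_m * ifelse(mediated0 <- class_vec == "mediated",
                        runif_range(G, config$mediated_mrna_age_range),
                        runif_range(G, config$mrna_age_range)) # natural log / year
  b_p <- sgn_p * runif_range(G, config$protein_age_range)   # direct protein term
  s_m <- stats::rnorm(G, 0, config$sex_sd)                  # sex effect, latent scale
  disp <- runif_range(G, config$dispersion_range)
  base <- runif_range(G, config$baseline_log_range)
  beff <- stats::rnorm(G, 0, config$batch_sd)

  sex_c <- ifelse(metadata$sex == "F", 0.5, -0.5)
  batch_c <- ifelse(metadata$batch == "B2", 1, 0)
  log_sf <- stats::rnorm(n, 0, config$libsize_sd)
  tag_eff <- stats::rnorm(16, 0, config$tag_sd)[as.integer(metadata$tag)]
  gen_eff <- stats::rnorm(5, 0, config$generation_sd)[as.integer(metadata$generation)]

  mediated <- class_vec == "mediated"
  mrna <- matrix(0L, G, n, dimnames = list(gene_id, metadata$sample_id))
  protein <- matrix(0, G, n, dimnames = list(gene_id, metadata$sample_id))
  for (g in seq_len(G)) {
    u <- stats::rnorm(n, 0, config$bio_sd)
    latent <- u + s_m[g] * sex_c + if (mediated[g]) b_m[g] * metadata$age_coded else 0
    direct_age <- if (mediated[g]) 0 else b_m[g] * metadata$age_coded
    log_mu <- base[g] + direct_age + latent + beff[g] * batch_c + log_sf
    mrna[g, ] <- stats::rnbinom(n, size = 1 / disp[g], mu = exp(log_mu))
    protein[g, ] <- config$lambda * latent + b_p[g] * metadata$age_coded +
      tag_eff + gen_eff + stats::rnorm(n, 0, config$protein_noise_sd)
  }

  truth <- data.frame(
    gene_id = gene_id, class = class_vec,
    mrna_slope = b_m, mrna_slope_log2 = b_m / log(2),
    protein_slope = ifelse(mediated, config$lambda * b_m, b_p),
    lambda = config$lambda, mediated = mediated,
    sex_mrna = s_m, sex_protein = config$lambda * s_m,
    dispersion = disp, stringsAsFactors = FALSE)

  list(mrna = mrna, protein = protein, metadata = metadata, truth = truth)
}

#' Simulate cell-type mean reference profiles with known markers
#'
#' Builds a gene-by-cell-type matrix of mean expression profiles in which each
#' type has `markers_per_type` marker genes expressed `fold`-fold above every
#' other type, and all remaining genes have exchangeable means.
#'
#' @param n_types Number of cell types (>= 1).
#' @param n_genes Total genes; must be at least `n_types * markers_per_type`.
#' @param markers_per_type Markers assigned to each type.
#' @param seed Random seed.
#' @param fold Marker over-expression factor (>= 5 keeps markers unambiguous).
#' @return List with `profiles` (gene x type matrix) and `markers`
#'   (data frame `gene`, `cell_type`).
#' @export
simulate_reference_profiles <- function(n_types, n_genes, markers_per_type,
                                        seed = 1L, fold = 8) {
  if (n_types < 1 || markers_per_type < 1) stop("counts must be positive")
  if (n_types * markers_per_type > n_genes)
    stop("infeasible: n_types * markers_per_type exceeds n_genes")
  set.seed(seed)
  genes <- sprintf("gene%04d", seq_len(n_genes))
  types <- paste0("type", seq_len(n_types))
  base <- exp(stats::rnorm(n_genes, log(5), 0.5))
  profiles <- matrix(rep(base, n_types), n_genes, n_types,
                     dimnames = list(genes, types))
  profiles <- profiles * exp(matrix(stats::rnorm(n_genes * n_types, 0, 0.05),
                                    n_genes, n_types))
  marker_idx <- sample(n_genes, n_types * markers_per_type)
  assignment <- rep(seq_len(n_types), each = markers_per_type)
  for (k in seq_along(marker_idx))
    profiles[marker_idx[k], assignment[k]] <-
      fold * max(profiles[marker_idx[k], ])
  list(profiles = profiles,
       markers = data.frame(gene = genes[marker_idx],
                            cell_type = types[assignment],
                            stringsAsFactors = FALSE))
}

#' Simulate urinary phenotypes linked to a protein
#'
#' Generates per-sample creatinine (log-normal, positive), phosphate whose
#' log-concentration follows `alpha + effect * scale(protein_row) + sex +
#' noise` and scales with creatinine (so creatinine adjustment is
#' meaningful), and albumin drawn so that a configurable majority of samples
#' fall below a detection-like threshold.
#'
#' @param metadata Cohort metadata (needs `sample_id` and `sex`).
#' @param protein_row Abundance vector aligned to `metadata` rows.
#' @param effect Standardized slope of log phosphate on the protein.
#' @param seed Random seed.
#' @param albumin_below_frac Target fraction of samples below
#'   `albumin_threshold` (default 157/188).
#' @param albumin_threshold Detection-like threshold (default 1).
#' @return Data frame `sample_id`, `albumin`, `phosphate`, `creatinine`.
#' @export
simulate_urine <- function(metadata, protein_row, effect, seed = 1L,
                           albumin_below_frac = 157 / 188,
                           albumin_threshold = 1) {
  n <- nrow(metadata)
  if (length(protein_row) != n)
    stop("`protein_row` must align with `metadata` rows")
  set.seed(seed)
  sex_c <- ifelse(metadata$sex == "F", 0.5, -0.5)
  creatinine <- exp(stats::rnorm(n, 0, 0.4))
  z <- as.numeric(scale(protein_row))
  phosphate <- exp(1 + effect * z + 0.2 * sex_c + stats::rnorm(n, 0, 0.3)) *
    creatinine
  mu_alb <- log(albumin_threshold) - 1 * stats::qnorm(albumin_below_frac)
  albumin <- exp(stats::rnorm(n, mu_alb, 1))
  data.frame(sample_id = metadata$sample_id, albumin = albumin,
             phosphate = phosphate, creatinine = creatinine,
             stringsAsFactors = FALSE)
}
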