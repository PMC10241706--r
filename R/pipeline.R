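# End-to-end orchestration: simulate (or load) two cohorts, merge and
# normalize, label, factorize, stratify, score, associate, and run the
# survival battery, writing tidy CSV artifacts plus a manifest. Stage
# seeds are derived from the master seed by fixed offsets so any stage can
# be re-run in isolation.

STAGE_SEED_OFFSETS <- c(metagenes = 11L, cohort1 = 23L, cohort2 = 37L,
                        clinical = 53L, fit = 71L, cv = 89L)

#' Default run configuration for simulate mode
#'
#' Generator settings follow the reference synthetic conditions used
#' throughout the package: 500 genes, 8 metagenes, marker fold-change 10,
#' Dirichlet concentration (8, 1, 1, 1) with a dominant component,
#' expression noise sd 0.1, two cohorts of equal size differing by a
#' multiplicative scale (1.6) and additive offset (0.5), survival
#' calibrated to an extreme-quartile hazard ratio of 2, administrative
#' censoring over 300 months.
#'
#' @param n_per_cohort Samples per cohort (default 100).
#' @param master_seed Master seed; all stage seeds derive from it.
#' @param k,lam ssNMF hyperparameters used when \code{select} is FALSE.
#' @param select Run cross-validated hyperparameter selection (slower).
#' @param k_grid,lam_grid CV grids used when \code{select} is TRUE.
#' @param target_hr Extreme-quartile hazard ratio the survival generator
#'   is calibrated to.
#' @return A named list of class \code{run_config}.
#' @export
default_run_config <- function(n_per_cohort = 100L, master_seed = 1L,
                               k = 8L, lam = 1, select = FALSE,
                               k_grid = c(4L, 8L, 12L),
                               lam_grid = c(0.1, 1, 10),
                               target_hr = 2) {
  structure(list(mode = "simulate",
                 m = 500L, k_true = 8L, separation = 10,
                 purity_alpha = c(8, 1, 1, 1), noise_sd = 0.1,
                 n_per_cohort = as.integer(n_per_cohort),
                 batch_scale2 = 1.6, batch_offset2 = 0.5,
                 censor_window = 300, target_hr = target_hr,
                 normalization = "zscore",
                 k = as.integer(k), lam = lam, select = select,
                 k_grid = k_grid, lam_grid = lam_grid,
                 master_seed = as.integer(master_seed)),
            class = "run_config")
}

#' Run configuration for user-supplied data
#'
#' @param expression_paths Named character vector of expression TSV paths
#'   (one per cohort; names are the cohort tags).
#' @param clinical_paths Clinical TSV paths aligned with
#'   \code{expression_paths}.
#' @param centroid_path PAM50 centroid TSV (default: packaged synthetic
#'   fixture).
#' @param master_seed Master seed.
#' @param k,lam,select,k_grid,lam_grid As in
#'   \code{\link{default_run_config}}.
#' @return A \code{run_config} with \code{mode = "real"}.
#' @export
real_run_config <- function(expression_paths, clinical_paths,
                            centroid_path = pam50_centroid_fixture(),
                            master_seed = 1L, k = 8L, lam = 1,
                            select = FALSE, k_grid = c(4L, 8L, 12L),
                            lam_grid = c(0.1, 1, 10)) {
  structure(list(mode = "real",
                 expression_paths = expression_paths,
                 clinical_paths = clinical_paths,
                 centroid_path = centroid_path,
                 normalization = "zscore",
                 k = as.integer(k), lam = lam, select = select,
                 k_grid = k_grid, lam_grid = lam_grid,
                 master_seed = as.integer(master_seed)),
            class = "run_config")
}

simulate_bundles <- function(config) {
  seed0 <- config$master_seed
  truth <- generate_metagenes(config$m, config$k_true,
                              separation = config$separation,
                              seed = seed0 + STAGE_SEED_OFFSETS[["metagenes"]])
  gene_ids <- synthetic_gene_ids(truth)
  b1 <- generate_cohort(truth, config$n_per_cohort,
                        purity_alpha = config$purity_alpha,
                        noise_sd = config$noise_sd, cohort_id = "simA",
                        batch_scale = 1, batch_offset = 0,
                        gene_ids = gene_ids,
                        seed = seed0 + STAGE_SEED_OFFSETS[["cohort1"]])
  b2 <- generate_cohort(truth, config$n_per_cohort,
                        purity_alpha = config$purity_alpha,
                        noise_sd = config$noise_sd, cohort_id = "simB",
                        batch_scale = config$batch_scale2,
                        batch_offset = config$batch_offset2,
                        gene_ids = gene_ids,
                        seed = seed0 + STAGE_SEED_OFFSETS[["cohort2"]])
  # survival calibrated on the pooled LumA-dominant cases: the downstream
  # survival stage stratifies the LumA subset by pLumA quartile
  P <- cbind(b1$truth$true_proportions, b2$truth$true_proportions)
  luma <- c(as.character(b1$labels), as.character(b2$labels)) == "LumA"
  hc <- calibrate_hazard(P[, luma, drop = FALSE],
                         target_hr = config$target_hr)
  b1$truth$hazard_coefficient <- hc
  b2$truth$hazard_coefficient <- hc
  cl <- generate_clinical(b1$truth, P, hazard_coefficient = hc,
                          censor_window = config$censor_window,
                          seed = seed0 + STAGE_SEED_OFFSETS[["clinical"]])
  n1 <- ncol(b1$truth$true_proportions)
  b1$clinical <- validate_clinical(cl[seq_len(n1), , drop = FALSE])
  b2$clinical <- validate_clinical(cl[-seq_len(n1), , drop = FALSE])
  list(b1, b2)
}

#' Run the full admixture pipeline
#'
#' Stages, in order: simulate or load two cohorts; merge on shared genes
#' with within-cohort z-scoring; min-shift to nonnegative; (real mode)
#' assign PAM50 labels by nearest centroid and drop Normal/Claudin-low;
#' fit ssNMF (optionally after CV hyperparameter selection); derive the
#' admixture table (proportions, entropy, purity quartiles, eQ4, DRC);
#' score the molecular panel; compare features across purity quartiles;
#' fit KM and Cox models. Artifacts are written as tidy CSVs into
#' \code{out_dir} together with a JSON manifest (config, seeds, input
#' checksums, artifact list).
#'
#' @param config A \code{run_config}.
#' @param out_dir Output directory (created; default: a temporary
#'   directory).
#' @return A list of class \code{pipeline_run} holding every intermediate
#'   (bundles, model, admixture table, comparisons, survival fits) plus
#'   \code{out_dir} and \code{manifest}.
#' @export
run_pipeline <- function(config, out_dir = tempfile("admix_run_")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(master_seed = config$master_seed,
                   mode = config$mode, artifacts = character(0))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest$failed_stage <<- name
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  if (config$mode == "simulate") {
    bundles <- stage("simulate", simulate_bundles(config))
  } else {
    bundles <- stage("load", {
      paths <- c(config$expression_paths, config$clinical_paths)
      missing <- paths[!file.exists(paths)]
      if (length(missing) > 0L)
        stop("input file(s) not found: ", paste(missing, collapse = ", "))
      manifest$input_checksums <- as.list(tools::md5sum(paths))
      lapply(seq_along(config$expression_paths), function(i) {
        tag <- names(config$expression_paths)[i]
        ex <- read_expression(config$expression_paths[i], cohort = tag)
        cl <- read_clinical(config$clinical_paths[i])
        structure(list(expression = ex, clinical = cl, labels = NULL,
                       onehot = NULL, cohort_id = tag, truth = NULL),
                  class = "cohort_bundle")
      })
    })
  }
  merged <- stage("merge", merge_cohorts(bundles,
                                         normalization = config$normalization))
  merged$expression <- stage("nonnegative", prepare_nonnegative(merged$expression))
  if (config$mode == "real") {
    centroids <- stage("centroids", read_centroids(config$centroid_path))
    lab <- stage("assign_pam50", assign_pam50(merged$expression, centroids))
    merged$labels <- lab$call
    merged <- stage("filter_subtypes", filter_subtypes(merged))
    merged$onehot <- onehot_matrix(merged$labels)
    correlations <- lab$correlations[, merged$expression$sample_ids, drop = FALSE]
  } else {
    centroids <- estimate_centroids(merged$expression, merged$labels)
    correlations <- NULL
  }
  X <- merged$expression$values
  L <- merged$onehot
  seed_fit <- config$master_seed + STAGE_SEED_OFFSETS[["fit"]]
  if (isTRUE(config$select)) {
    sel <- stage("select_hyperparameters",
                 select_hyperparameters(X, L, k_grid = config$k_grid,
                                        lam_grid = config$lam_grid,
                                        seed = config$master_seed +
                                          STAGE_SEED_OFFSETS[["cv"]]))
    k_use <- sel$k; lam_use <- sel$lam
  } else {
    sel <- NULL; k_use <- config$k; lam_use <- config$lam
  }
  model <- stage("fit_ssnmf",
                 fit_ssnmf(X, L, ssnmf_config(k = k_use, lam = lam_use,
                                              seed = seed_fit)))
  P <- stage("admixture", admixture_proportions(
    model, sample_ids = merged$expression$sample_ids))
  drc <- stage("drc", tryCatch({
    lab_chr <- as.character(merged$labels)
    cov <- pooled_covariance(t(X), lab_chr)
    cm <- centroids$centroid_matrix[merged$expression$gene_ids, , drop = FALSE]
    vapply(seq_len(ncol(X)), function(j)
      distance_ratio_criteria(X[, j], cm, cov, lab_chr[j]), numeric(1L))
  }, error = function(e) {
    message("DRC unavailable: ", conditionMessage(e))
    NULL
  }))
  # purity stratification and every downstream comparison concern the
  # LumA-assigned cases only; proportions for all samples stay available
  luma <- which(as.character(merged$labels) == "LumA")
  if (length(luma) < 8L)
    stop("pipeline needs >= 8 LumA-assigned cases for the purity analyses (got ",
         length(luma), ")")
  P_luma <- P[, luma, drop = FALSE]
  admix <- stage("admixture_table",
                 admixture_table(P_luma,
                                 sample_ids = merged$expression$sample_ids[luma],
                                 cohort = merged$expression$cohort[luma],
                                 drc = drc[luma]))
  panel <- stage("score_panel", tryCatch(
    score_panel(merged$expression, centroids, correlations = correlations),
    error = function(e) {
      message("score panel skipped: ", conditionMessage(e))
      NULL
    }))
  if (!is.null(panel)) admix <- merge(admix, panel, by = "sample_id", sort = FALSE)
  comparisons <- survfit_q <- coxq <- coxq_adj <- NULL
  if (!is.null(merged$clinical)) {
    cl <- as.data.frame(merged$clinical)
    cl <- cl[match(admix$sample_id, cl$sample_id), ]
    q <- admix$purity_quartile
    feats <- intersect(c("age", "node_positive", "size_gt20", "stage_gt1",
                         "er_pos", "pr_pos", "her2_pos", "tnbc",
                         "mut_TP53", "mut_PIK3CA", "mut_CBFB"), names(cl))
    comparisons <- stage("compare_groups", compare_groups(cl, q, feats))
    survfit_q <- stage("km", km_fit(cl$os_months, cl$os_event,
                                    paste0("Q", q)))
    coxq <- stage("cox_unadjusted", cox_hr(cl$os_months, cl$os_event, q))
    coxq_adj <- stage("cox_adjusted",
                      cox_hr(cl$os_months, cl$os_event, q,
                             covariates = cl[, intersect(
                               c("age", "size_gt20", "stage_gt1"), names(cl))]))
  }
  # ---- artifacts -------------------------------------------------------
  emit <- function(obj, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(obj, p, row.names = FALSE)
    manifest$artifacts <<- c(manifest$artifacts, name)
    p
  }
  emit(admix, "admixture_table.csv")
  hist_df <- do.call(rbind, lapply(SUBTYPES4, function(s) {
    h <- proportion_histogram(P_luma[s, ])
    cbind(subtype = s, h)
  }))
  emit(hist_df, "proportion_histograms.csv")
  if (!is.null(comparisons)) emit(comparisons, "quartile_comparisons.csv")
  if (!is.null(coxq)) {
    hr_tab <- rbind(cbind(model = "unadjusted", coxq$contrasts,
                          trend_p = coxq$trend_p),
                    cbind(model = "adjusted", coxq_adj$contrasts,
                          trend_p = coxq_adj$trend_p))
    emit(hr_tab, "cox_hazard_ratios.csv")
    emit(survfit_q$curves, "km_curves.csv")
  }
  # basal-marker cross-classification (EGFR when measured)
  gene <- if ("EGFR" %in% merged$expression$gene_ids) "EGFR" else NULL
  if (!is.null(gene)) {
    qb <- quartile_stratify(P_luma["Basal", ])
    cc <- cross_classified_means(X[gene, luma], admix$purity_quartile, qb)
    cc_df <- data.frame(pLumA_quartile = rep(rownames(cc$means),
                                             ncol(cc$means)),
                        pBasal_quartile = rep(colnames(cc$means),
                                              each = nrow(cc$means)),
                        mean_expression = as.vector(cc$means),
                        n = as.vector(cc$counts))
    emit(cc_df, "cross_classified_means.csv")
  }
  model_dir <- file.path(out_dir, "model")
  write_ssnmf_model(model, model_dir)
  manifest$artifacts <- c(manifest$artifacts,
                          file.path("model", c("A.tsv", "B.tsv", "S.tsv",
                                               "config.json",
                                               "objective_trace.csv")))
  manifest$k <- k_use; manifest$lam <- lam_use
  manifest$n <- ncol(X); manifest$m <- nrow(X)
  manifest$stage_seed_offsets <- as.list(STAGE_SEED_OFFSETS)
  manifest$package_version <- as.character(utils::packageVersion("subtypeAdmix"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  structure(list(config = config, bundles = bundles, merged = merged,
                 model = model, selection = sel, proportions = P,
                 admixture = admix, comparisons = comparisons,
                 km = survfit_q, cox = coxq, cox_adjusted = coxq_adj,
                 out_dir = out_dir, manifest = manifest),
            class = "pipeline_run")
}

#' Concordance of the purity metrics
#'
#' Spearman correlations among pLumA, Shannon entropy (negated, so that
#' higher = purer for every metric) and, when present, negated DRC, plus
#' the cross-tabulation of the quartile strata each metric induces.
#'
#' @param admix An admixture table from \code{\link{admixture_table}} /
#'   \code{\link{run_pipeline}}.
#' @return A list: \code{spearman} (correlation matrix),
#'   \code{quartile_crosstab} (pLumA vs entropy quartiles), \code{note}.
#' @export
compare_purity_metrics <- function(admix) {
  metrics <- cbind(pLumA = admix$pLumA, neg_entropy = -admix$entropy_bits)
  note <- NULL
  if (!all(is.na(admix$drc))) {
    metrics <- cbind(metrics, neg_drc = -admix$drc)
  } else note <- "DRC absent; comparison limited to pLumA vs entropy"
  rho <- stats::cor(metrics, method = "spearman")
  qa <- quartile_stratify(admix$pLumA)
  qe <- quartile_stratify(-admix$entropy_bits)
  list(spearman = rho, quartile_crosstab = table(pLumA_q = qa, entropy_q = qe),
       note = note)
}
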