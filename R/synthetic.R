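# Synthetic two-cohort generator with known ground-truth subtype admixture.
# Bulk profiles are modeled as nonnegative mixtures of block-structured
# metagenes; clinical covariates and survival are linked to the admixture.

#' Generate a block-structured nonnegative metagene basis
#'
#' Builds the ground truth for a synthetic cohort: \code{k_true} nonnegative
#' metagenes over \code{m} genes, each with a disjoint block of roughly
#' \code{m / k_true} marker genes whose weights are elevated by the
#' \code{separation} fold-change over background. Metagenes are assigned to
#' the four subtypes round-robin, so every subtype owns at least one
#' metagene when \code{k_true >= subtype_count}.
#'
#' @param m Number of genes (\code{m >= k_true}).
#' @param k_true Number of metagenes (\code{k_true >= subtype_count}).
#' @param subtype_count Number of subtypes (default 4).
#' @param separation Fold-change (>= 1) of marker-block weights over
#'   background; 1 means no block structure.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return An object of class \code{synthetic_truth}: list with
#'   \code{metagene_basis} (m x k_true), \code{subtype_of_metagene}
#'   (integer vector, values 1..subtype_count), \code{marker_block}
#'   (gene -> metagene index), \code{separation}, \code{seed}, and slots
#'   filled later by \code{\link{generate_cohort}} /
#'   \code{\link{calibrate_hazard}} (\code{true_proportions},
#'   \code{hazard_coefficient}, \code{baseline_rate}).
#' @export
generate_metagenes <- function(m, k_true, subtype_count = 4L,
                               separation = 10, seed = 1L) {
  if (m < k_true) stop("invalid dimensions: m (", m, ") < k_true (", k_true, ")")
  if (k_true < subtype_count)
    stop("invalid dimensions: k_true < subtype_count")
  if (separation < 1) stop("separation must be >= 1")
  rng <- local_rng(seed)
  # disjoint marker blocks of near-equal size, remainder to the first blocks
  block <- rep(seq_len(k_true), length.out = m)
  block <- sort(block)
  basis <- matrix(stats::rgamma(m * k_true, shape = 2, rate = 2),
                  nrow = m, ncol = k_true)
  for (j in seq_len(k_true)) basis[block == j, j] <- basis[block == j, j] * separation
  subtype_of_metagene <- rep(seq_len(subtype_count), length.out = k_true)
  structure(list(metagene_basis = basis,
                 subtype_of_metagene = subtype_of_metagene,
                 marker_block = block,
                 separation = separation,
                 true_proportions = NULL,
                 hazard_coefficient = 0,
                 baseline_rate = log(2) / 230,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

local_rng <- function(seed) set.seed(as.integer(seed))

#' Draw per-sample subtype admixture and expression for one cohort
#'
#' Each sample gets a uniformly drawn dominant subtype and a Dirichlet
#' 4-vector of subtype proportions whose concentration is
#' \code{purity_alpha} rotated so the dominant component carries the largest
#' concentration. Proportions are expanded to metagene mixing weights
#' (split equally across the metagenes a subtype owns), multiplied through
#' the metagene basis, scaled and offset per cohort (batch effect), and
#' perturbed by centered Gaussian noise clipped at zero so the matrix stays
#' nonnegative. The label is the dominant subtype.
#'
#' @param truth A \code{synthetic_truth} from \code{\link{generate_metagenes}}.
#' @param n Samples to draw (>= 8).
#' @param purity_alpha Strictly positive Dirichlet concentration 4-vector;
#'   first element is the dominant component's concentration. Default
#'   \code{c(8, 1, 1, 1)} gives a dominant subtype with non-zero admixture.
#' @param noise_sd Standard deviation of the additive expression noise.
#' @param cohort_id Cohort tag.
#' @param batch_scale Multiplicative cohort batch effect (> 0).
#' @param batch_offset Additive cohort batch effect.
#' @param gene_ids Gene identifiers (default \code{g0001..}); see
#'   \code{\link{synthetic_gene_ids}} for a naming that embeds marker
#'   symbols so classifier and signature stages can run on synthetic data.
#' @param seed Integer seed.
#' @return A \code{cohort_bundle}: list with \code{expression}
#'   (\code{expr_matrix}), \code{labels} (factor over the four subtypes),
#'   \code{onehot} (4 x n), \code{cohort_id}, and \code{truth} whose
#'   \code{true_proportions} (4 x n, columns sum to 1) record the draw.
#' @export
generate_cohort <- function(truth, n, purity_alpha = c(8, 1, 1, 1),
                            noise_sd = 0.1, cohort_id = "cohort1",
                            batch_scale = 1, batch_offset = 0,
                            gene_ids = NULL, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (n < 8L) stop("n must be >= 8")
  if (length(purity_alpha) != 4L || any(purity_alpha <= 0))
    stop("invalid parameter: purity_alpha must be 4 strictly positive values")
  if (batch_scale <= 0) stop("batch_scale must be positive")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  rng <- local_rng(seed)
  m <- nrow(truth$metagene_basis)
  k_true <- ncol(truth$metagene_basis)
  dominant <- sample.int(4L, n, replace = TRUE)
  P <- matrix(0, nrow = 4L, ncol = n)
  for (i in seq_len(n)) {
    alpha <- rep(purity_alpha[-1L], length.out = 4L)
    alpha[dominant[i]] <- purity_alpha[1L]
    g <- stats::rgamma(4L, shape = alpha, rate = 1)
    if (sum(g) <= 0) g <- alpha   # measure-zero guard
    # enforce dominance: the labeled subtype must carry the largest mass,
    # so the recorded label always equals the argmax of true_proportions
    mx <- which.max(g)
    if (mx != dominant[i]) g[c(mx, dominant[i])] <- g[c(dominant[i], mx)]
    P[, i] <- g / sum(g)
  }
  rownames(P) <- SUBTYPES4
  # expand subtype proportions to metagene weights: equal split within owner
  W <- matrix(0, nrow = k_true, ncol = n)
  for (s in 1:4) {
    own <- which(truth$subtype_of_metagene == s)
    W[own, ] <- matrix(rep(P[s, ] / length(own), each = length(own)),
                       nrow = length(own))
  }
  X <- truth$metagene_basis %*% W
  X <- X * batch_scale + batch_offset
  if (noise_sd > 0) X <- X + matrix(stats::rnorm(m * n, sd = noise_sd), m, n)
  X <- pmax(X, 0)
  if (is.null(gene_ids)) gene_ids <- sprintf("g%04d", seq_len(m))
  if (length(gene_ids) != m) stop("gene_ids length must equal m")
  sample_ids <- sprintf("%s_s%04d", cohort_id, seq_len(n))
  expr <- expr_matrix(X, gene_ids = gene_ids, sample_ids = sample_ids,
                      cohort = cohort_id)
  labels <- factor(SUBTYPES4[dominant], levels = SUBTYPES4)
  truth$true_proportions <- P
  colnames(truth$true_proportions) <- sample_ids
  structure(list(expression = expr,
                 labels = labels,
                 onehot = onehot_matrix(labels),
                 clinical = NULL,
                 cohort_id = cohort_id,
                 truth = truth),
            class = "cohort_bundle")
}

#' One-hot encode subtype calls
#'
#' @param labels Factor or character vector over the four modeled subtypes.
#' @return A 4 x n 0/1 matrix, rows LumA, LumB, HER2, Basal; each column has
#'   exactly one 1.
#' @export
onehot_matrix <- function(labels) {
  labels <- factor(as.character(labels), levels = SUBTYPES4)
  if (anyNA(labels)) stop("labels outside the four modeled subtypes")
  L <- matrix(0, nrow = 4L, ncol = length(labels),
              dimnames = list(SUBTYPES4, names(labels)))
  L[cbind(as.integer(labels), seq_along(labels))] <- 1
  L
}

#' Calibrate the admixture log-hazard to a target extreme-quartile ratio
#'
#' Chooses the per-unit log-hazard on (1 - pLumA) so that the mean
#' log-hazard difference between the lowest and highest pLumA quartiles of
#' the supplied proportions equals \code{log(target_hr)}.
#'
#' @param proportions 4 x n matrix of subtype proportions (rows named,
#'   \code{"LumA"} first).
#' @param target_hr Target hazard ratio between the most admixed and purest
#'   quartile (default 2, the effect size used throughout).
#' @return The hazard coefficient (per unit of 1 - pLumA).
#' @export
calibrate_hazard <- function(proportions, target_hr = 2) {
  admix <- 1 - proportions["LumA", ]
  q <- quartile_stratify(proportions["LumA", ])
  delta <- mean(admix[q == 1L]) - mean(admix[q == 4L])
  if (delta <= 0) stop("degenerate proportions: no purity spread to calibrate")
  log(target_hr) / delta
}

#' Simulate clinical covariates and survival linked to admixture
#'
#' Binary covariates follow logistic links in the admixture mass
#' (1 - pLumA) and in the alternate-subtype proportions; age is Gaussian
#' with configurable subtype shifts; overall survival is exponential with
#' log-hazard \code{hazard_coefficient * (1 - pLumA)} on top of the baseline
#' rate, censored administratively at a uniform time over
#' \code{censor_window} months.
#'
#' @param truth A \code{synthetic_truth} (supplies \code{baseline_rate}).
#' @param proportions 4 x n matrix of subtype proportions, columns sum to 1.
#' @param effect_config Named list of link coefficients. Recognized entries:
#'   for each binary covariate \code{<name>} a vector
#'   \code{c(intercept, admix, lumb, her2, basal)} applied on the logit
#'   scale to (1, 1 - pLumA, pLumB, pHER2, pBasal); \code{age_mean},
#'   \code{age_sd}, \code{age_effects} (length-4 mean shift per unit
#'   subtype proportion). Use \code{\link{default_effect_config}} for the
#'   reference setting.
#' @param hazard_coefficient Per-unit log-hazard for (1 - pLumA); default
#'   takes the value stored in \code{truth}.
#' @param censor_window Length (months) of the uniform administrative
#'   censoring window; 0 means every event is observed.
#' @param sample_ids Sample identifiers (default from the proportion
#'   column names).
#' @param seed Integer seed.
#' @return A \code{clinical_table} with the mandatory columns of
#'   \code{\link{read_clinical}}.
#' @export
generate_clinical <- function(truth, proportions,
                              effect_config = default_effect_config(),
                              hazard_coefficient = truth$hazard_coefficient,
                              censor_window = 300,
                              sample_ids = colnames(proportions),
                              seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (is.null(rownames(proportions))) rownames(proportions) <- SUBTYPES4
  n <- ncol(proportions)
  if (is.null(sample_ids)) sample_ids <- sprintf("s%04d", seq_len(n))
  if (length(sample_ids) != n)
    stop("alignment error: sample_ids length != number of proportion columns")
  sums <- colSums(proportions)
  if (any(abs(sums - 1) > 1e-8))
    stop("proportion columns must sum to 1")
  rng <- local_rng(seed)
  admix <- 1 - proportions["LumA", ]
  covars <- cbind(1, admix, proportions["LumB", ], proportions["HER2", ],
                  proportions["Basal", ])
  draw_binary <- function(beta) {
    eta <- as.vector(covars %*% beta)
    as.integer(stats::runif(n) < stats::plogis(eta))
  }
  cfg <- effect_config
  age <- stats::rnorm(n, mean = cfg$age_mean +
                        as.vector(t(proportions) %*% cfg$age_effects),
                      sd = cfg$age_sd)
  df <- data.frame(sample_id = sample_ids,
                   age = round(age, 1),
                   stringsAsFactors = FALSE)
  for (nm in names(cfg$binary)) df[[nm]] <- draw_binary(cfg$binary[[nm]])
  df$tnbc <- as.integer(df$er_pos == 0 & df$pr_pos == 0 & df$her2_pos == 0)
  rate <- truth$baseline_rate * exp(hazard_coefficient * admix)
  t_event <- stats::rexp(n, rate = rate)
  if (censor_window > 0) {
    t_cens <- stats::runif(n, 0, censor_window)
    df$os_months <- pmin(t_event, t_cens)
    df$os_event <- as.integer(t_event <= t_cens)
  } else {
    df$os_months <- t_event
    df$os_event <- 1L
  }
  validate_clinical(df, where = "generated clinical table")
}

#' Reference link coefficients for the clinical generator
#'
#' Logistic-link coefficients \code{c(intercept, 1 - pLumA, pLumB, pHER2,
#' pBasal)} chosen to mimic the direction and rough strength of the
#' admixture associations seen in luminal-A breast cancer cohorts: admixed
#' tumors are more often node positive, larger, higher stage and
#' TP53-mutant; HER2 admixture tracks HER2 positivity; LumB admixture
#' tracks PR negativity; basal admixture tracks younger age; PIK3CA and
#' CBFB mutations enrich in pure tumors.
#'
#' @return A list with elements \code{binary} (named list of length-5
#'   coefficient vectors), \code{age_mean}, \code{age_sd},
#'   \code{age_effects}.
#' @export
default_effect_config <- function() {
  list(binary = list(
         node_positive = c(-0.5, 0.8, 0, 0, 0.6),
         size_gt20     = c(-0.3, 1.2, 0, 0, 0),
         stage_gt1     = c( 0.2, 1.0, 0, 0, 0),
         er_pos        = c( 3.5, 0, 0, -1.0, 0),
         pr_pos        = c( 1.8, 0, -1.5, -0.8, 0),
         her2_pos      = c(-3.2, 0, 0, 2.5, 0.8),
         mut_TP53      = c(-3.0, 1.8, 0, 1.0, 0.4),
         mut_PIK3CA    = c( 0.8, -1.5, 0, 0, -0.5),
         mut_CBFB      = c(-2.5, -1.0, 0, 0, -0.5)),
       age_mean = 58, age_sd = 10,
       age_effects = c(LumA = 2.5, LumB = 5, HER2 = 5, Basal = -3))
}

#' Null link coefficients (no admixture effect on any covariate)
#' @return An effect configuration with all non-intercept coefficients zero.
#' @export
null_effect_config <- function() {
  cfg <- default_effect_config()
  cfg$binary <- lapply(cfg$binary, function(b) c(b[1L], 0, 0, 0, 0))
  cfg$age_effects <- c(LumA = 0, LumB = 0, HER2 = 0, Basal = 0)
  cfg
}

#' Write a cohort bundle to disk
#'
#' Emits the expression TSV, the clinical TSV (if present), and a truth
#' JSON (proportions, parameters, seed) into \code{dir}.
#'
#' @param bundle A \code{cohort_bundle}.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(expression = file.path(dir, paste0(bundle$cohort_id, "_expression.tsv")))
  write_expression(bundle$expression, paths[["expression"]])
  if (!is.null(bundle$clinical)) {
    paths[["clinical"]] <- file.path(dir, paste0(bundle$cohort_id, "_clinical.tsv"))
    write_clinical(bundle$clinical, paths[["clinical"]])
  }
  if (!is.null(bundle$truth)) {
    paths[["truth"]] <- file.path(dir, paste0(bundle$cohort_id, "_truth.json"))
    tr <- bundle$truth
    jsonlite::write_json(list(true_proportions = tr$true_proportions,
                              subtype_of_metagene = tr$subtype_of_metagene,
                              separation = tr$separation,
                              hazard_coefficient = tr$hazard_coefficient,
                              baseline_rate = tr$baseline_rate,
                              seed = tr$seed),
                         paths[["truth"]], digits = NA, auto_unbox = TRUE)
  }
  invisible(paths)
}

# Curated subtype marker symbols used to name synthetic genes: luminal
# markers land in LumA-owned metagene blocks, proliferation genes in
# LumB-owned blocks, the HER2 amplicon in HER2 blocks and basal markers in
# Basal blocks, so nearest-centroid calls and signature scores behave
# coherently on simulated cohorts.
SUBTYPE_MARKER_SYMBOLS <- list(
  LumA = c("ESR1", "PGR", "FOXA1", "MLPH", "NAT1", "SLC39A6", "MAPT",
           "BCL2", "BLVRA", "CXXC5", "GPR160", "BAG1", "MDM2", "TMEM45B",
           "SCUBE2", "GSTM1"),
  LumB = c("BIRC5", "CCNB1", "CDC20", "NUF2", "CEP55", "NDC80", "MKI67",
           "PTTG1", "RRM2", "TYMS", "UBE2C", "UBE2T", "ANLN", "CCNE1",
           "CDC6", "CENPF", "EXO1", "KIF2C", "MELK", "MYBL2", "ORC6",
           "AURKA"),
  HER2 = c("ERBB2", "GRB7", "FGFR4", "MMP11", "CTSL2", "CD68"),
  Basal = c("KRT5", "KRT14", "KRT17", "SFRP1", "FOXC1", "MIA", "CDH3",
            "EGFR", "PHGDH", "ACTR3B", "MYC"))

#' Gene identifiers embedding subtype marker symbols
#'
#' Produces a gene-id vector for \code{\link{generate_cohort}} in which
#' well-known subtype marker symbols (PAM50 panel members, the Oncotype DX
#' genes, EGFR, ...) are placed inside the marker blocks of metagenes
#' owned by their subtype; the remaining genes keep anonymous
#' \code{g0001}-style ids. This lets the PAM50 classifier, the signature
#' engine and marker-gene cross-classifications run on synthetic cohorts.
#'
#' @param truth A \code{synthetic_truth}.
#' @return Character vector of length m (unique).
#' @export
synthetic_gene_ids <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  m <- nrow(truth$metagene_basis)
  ids <- sprintf("g%04d", seq_len(m))
  for (s in seq_along(SUBTYPE_MARKER_SYMBOLS)) {
    own <- which(truth$subtype_of_metagene == s)
    pos <- which(truth$marker_block %in% own)
    sym <- SUBTYPE_MARKER_SYMBOLS[[s]]
    take <- min(length(sym), length(pos))
    if (take > 0L) ids[pos[seq_len(take)]] <- sym[seq_len(take)]
  }
  ids
}
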