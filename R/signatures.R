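# Generic recurrence-signature engine. Four formula kinds cover the score
# variables of interest: an unweighted gene-set mean (PAM50 proliferation),
# a linear combination of subtype-centroid correlations (PAM50 risk of
# recurrence), a grouped linear score with per-group floors and risk
# cutpoints (Oncotype DX style), and a template-correlation threshold call
# (MammaPrint style). Gene lists, coefficients, floors and cutpoints live
# in JSON definition files, keeping the engine auditable and the published
# constants replaceable.

#' Read a signature definition JSON
#'
#' Schema fields: \code{name}, \code{kind} (one of
#' \code{"mean_of_genes"}, \code{"centroid_correlation_combination"},
#' \code{"grouped_linear_score"}, \code{"template_correlation_threshold"}),
#' \code{genes}, and kind-specific entries: \code{coefficients} (named by
#' group or subtype), \code{groups} (gene -> group), \code{clipping}
#' (group -> floor), \code{intercept}, \code{scale_mult}, \code{scale_add},
#' \code{range} (2-vector clamp), \code{risk_cutpoints},
#' \code{risk_labels}, \code{template} (named gene -> value),
#' \code{threshold}.
#'
#' @param path JSON file path.
#' @return A list of class \code{signature_definition}.
#' @export
read_signature <- function(path) {
  sig <- jsonlite::read_json(path, simplifyVector = TRUE)
  kinds <- c("mean_of_genes", "centroid_correlation_combination",
             "grouped_linear_score", "template_correlation_threshold")
  if (is.null(sig$name) || is.null(sig$kind) || !sig$kind %in% kinds)
    stop("invalid signature definition: ", path)
  if (is.null(sig$genes) || length(sig$genes) == 0L)
    stop("signature '", sig$name, "' declares no genes")
  if (!is.null(sig$risk_cutpoints) &&
      is.unsorted(sig$risk_cutpoints, strictly = TRUE))
    stop("risk_cutpoints must be strictly increasing")
  class(sig) <- "signature_definition"
  sig
}

#' Path to a packaged signature definition
#'
#' Packaged definitions: \code{"proliferation_pam50"} (11-gene mean),
#' \code{"ror_pam50"} (centroid-correlation combination),
#' \code{"oncotype_dx"} (grouped linear, 21 genes),
#' \code{"mammaprint"} (template correlation; synthetic template).
#'
#' @param name Definition name.
#' @return Installed file path.
#' @export
signature_fixture <- function(name = c("proliferation_pam50", "ror_pam50",
                                       "oncotype_dx", "mammaprint")) {
  name <- match.arg(name)
  system.file("extdata", "signatures", paste0(name, ".json"),
              package = "subtypeAdmix", mustWork = TRUE)
}

sig_gene_values <- function(expr, genes, sig_name, min_frac = 0.5) {
  present <- intersect(genes, expr$gene_ids)
  if (length(present) < min_frac * length(genes))
    stop("coverage error: only ", length(present), " of ", length(genes),
         " genes of signature '", sig_name, "' are measured")
  missing <- setdiff(genes, present)
  if (length(missing) > 0L)
    warning("signature '", sig_name, "': ", length(missing),
            " gene(s) missing, scored over the rest", call. = FALSE)
  expr$values[present, , drop = FALSE]
}

#' Unweighted gene-set mean score
#'
#' Mean normalized expression over the signature genes (e.g. the PAM50
#' 11-gene proliferation score). Requires at least half the signature genes
#' to be measured; missing genes are dropped with a warning.
#'
#' @param expr An \code{expr_matrix} of normalized expression.
#' @param sig A \code{signature_definition} with kind
#'   \code{"mean_of_genes"}.
#' @return Named per-sample numeric vector.
#' @export
score_mean_of_genes <- function(expr, sig) {
  stopifnot(sig$kind == "mean_of_genes")
  v <- sig_gene_values(expr, sig$genes, sig$name)
  colMeans(v)
}

#' Centroid-correlation combination score
#'
#' A linear combination of per-sample correlations with the subtype
#' centroids, with coefficients keyed by subtype (the PAM50 risk-of-
#' recurrence construction). Correlations are computed over the genes
#' shared between expression and centroids with the centroid object's
#' configured correlation, or reused from an \code{\link{assign_pam50}}
#' result.
#'
#' @param expr An \code{expr_matrix}.
#' @param centroids A \code{pam50_centroids} object.
#' @param sig A \code{signature_definition} with kind
#'   \code{"centroid_correlation_combination"}; \code{coefficients} named
#'   by centroid column.
#' @param correlations Optional precomputed subtype x sample correlation
#'   matrix (from \code{assign_pam50}).
#' @return Named per-sample numeric vector. \code{scale_mult} and
#'   \code{scale_add}, if present in the definition, are applied as
#'   \code{scale_mult * score + scale_add}.
#' @export
score_centroid_combination <- function(expr, centroids, sig,
                                       correlations = NULL) {
  stopifnot(sig$kind == "centroid_correlation_combination")
  if (is.null(correlations)) {
    shared <- intersect(centroids$genes, expr$gene_ids)
    if (length(shared) < 2L) stop("too few shared centroid genes")
    correlations <- t(suppressWarnings(
      stats::cor(expr$values[shared, , drop = FALSE],
                 centroids$centroid_matrix[shared, , drop = FALSE],
                 method = centroids$correlation_kind)))
  }
  coefs <- unlist(sig$coefficients)
  missing <- setdiff(names(coefs), rownames(correlations))
  if (length(missing) > 0L)
    stop("missing centroid(s) for signature '", sig$name, "': ",
         paste(missing, collapse = ", "))
  score <- as.vector(coefs %*% correlations[names(coefs), , drop = FALSE])
  names(score) <- colnames(correlations)
  mult <- if (is.null(sig$scale_mult)) 1 else sig$scale_mult
  add <- if (is.null(sig$scale_add)) 0 else sig$scale_add
  mult * score + add
}

#' Grouped linear score with floors and risk categories
#'
#' Computes per-group gene means, applies per-group floors (clipping from
#' below, as in the Oncotype DX recurrence-score formula), combines the
#' groups linearly with the definition's coefficients plus intercept,
#' rescales (\code{scale_mult}, \code{scale_add}), clamps to \code{range}
#' when given, and categorizes by \code{risk_cutpoints} with a
#' lower-closed convention: a score exactly at a cutpoint belongs to the
#' higher category.
#'
#' When the definition carries \code{rescale_range} (a 2-vector), each
#' signature gene is first min-max rescaled across samples to that range.
#' This maps research-scale normalized expression onto the reference-
#' normalized scale the published floors and cutpoints were defined on;
#' absolute score levels then depend on the cohort and are not comparable
#' to the commercial assay.
#'
#' @param expr An \code{expr_matrix}.
#' @param sig A \code{signature_definition} with kind
#'   \code{"grouped_linear_score"}.
#' @return A data.frame: \code{sample_id}, \code{score}, \code{risk}
#'   (factor over the definition's \code{risk_labels}).
#' @export
score_grouped_linear <- function(expr, sig) {
  stopifnot(sig$kind == "grouped_linear_score")
  groups <- unlist(sig$groups)
  if (!all(sig$genes %in% names(groups)))
    stop("group map must cover every signature gene")
  coefs <- unlist(sig$coefficients)
  vals <- expr$values
  if (!is.null(sig$rescale_range)) {
    rr <- sig$rescale_range
    sel <- intersect(sig$genes, rownames(vals))
    v <- vals[sel, , drop = FALSE]
    lo <- apply(v, 1L, min); hi <- apply(v, 1L, max)
    span <- ifelse(hi > lo, hi - lo, 1)
    vals[sel, ] <- rr[1L] + (v - lo) / span * (rr[2L] - rr[1L])
  }
  group_means <- matrix(NA_real_, nrow = length(coefs), ncol = ncol(expr$values),
                        dimnames = list(names(coefs), expr$sample_ids))
  for (grp in names(coefs)) {
    gg <- names(groups)[groups == grp]
    present <- intersect(gg, rownames(vals))
    if (length(present) == 0L)
      stop("coverage error: no measured gene in group '", grp,
           "' of signature '", sig$name, "'")
    gm <- colMeans(vals[present, , drop = FALSE])
    floor_at <- sig$clipping[[grp]]
    if (!is.null(floor_at)) gm <- pmax(gm, floor_at)
    group_means[grp, ] <- gm
  }
  intercept <- if (is.null(sig$intercept)) 0 else sig$intercept
  raw <- intercept + as.vector(coefs %*% group_means)
  mult <- if (is.null(sig$scale_mult)) 1 else sig$scale_mult
  add <- if (is.null(sig$scale_add)) 0 else sig$scale_add
  score <- mult * raw + add
  if (!is.null(sig$range))
    score <- pmin(pmax(score, sig$range[1L]), sig$range[2L])
  risk <- NULL
  if (!is.null(sig$risk_cutpoints)) {
    labels <- sig$risk_labels
    if (is.null(labels))
      labels <- paste0("level", seq_len(length(sig$risk_cutpoints) + 1L))
    # lower-closed: score == cutpoint goes to the higher category
    idx <- findInterval(score, sig$risk_cutpoints, left.open = FALSE) + 1L
    risk <- factor(labels[idx], levels = labels)
  }
  data.frame(sample_id = expr$sample_ids, score = score, risk = risk,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Template-correlation risk call
#'
#' Correlates each sample with a good-prognosis template over the
#' signature genes (Pearson); samples whose correlation falls strictly
#' below the definition's threshold are called high risk (an index exactly
#' at the threshold is low risk).
#'
#' @param expr An \code{expr_matrix}.
#' @param sig A \code{signature_definition} with kind
#'   \code{"template_correlation_threshold"}; \code{template} maps genes to
#'   template values, \code{threshold} is the correlation cut.
#' @return A data.frame: \code{sample_id}, \code{index} (correlation in
#'   [-1, 1]), \code{high_risk} (logical).
#' @export
score_template_correlation <- function(expr, sig) {
  stopifnot(sig$kind == "template_correlation_threshold")
  template <- unlist(sig$template)
  present <- intersect(names(template), expr$gene_ids)
  if (length(present) < 0.5 * length(template))
    stop("coverage error: fewer than half the template genes are measured")
  idx <- suppressWarnings(
    as.vector(stats::cor(expr$values[present, , drop = FALSE],
                         template[present], method = "pearson")))
  data.frame(sample_id = expr$sample_ids, index = idx,
             high_risk = idx < sig$threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compute the full molecular score panel
#'
#' Applies the four packaged signature definitions (or user-supplied
#' replacements) to an expression matrix.
#'
#' @param expr An \code{expr_matrix} of normalized expression.
#' @param centroids A \code{pam50_centroids} object (for the ROR score).
#' @param correlations Optional precomputed centroid correlations.
#' @param definitions Named list of \code{signature_definition}s with
#'   entries \code{proliferation}, \code{ror}, \code{oncotype},
#'   \code{mammaprint}; defaults to the packaged fixtures.
#' @return A data.frame: sample_id, proliferation, ror, oncotype_rs,
#'   oncotype_risk, mammaprint_index, mammaprint_high_risk.
#' @export
score_panel <- function(expr, centroids, correlations = NULL,
                        definitions = list(
                          proliferation = read_signature(signature_fixture("proliferation_pam50")),
                          ror = read_signature(signature_fixture("ror_pam50")),
                          oncotype = read_signature(signature_fixture("oncotype_dx")),
                          mammaprint = read_signature(signature_fixture("mammaprint")))) {
  prolif <- score_mean_of_genes(expr, definitions$proliferation)
  ror <- score_centroid_combination(expr, centroids, definitions$ror,
                                    correlations = correlations)
  onc <- score_grouped_linear(expr, definitions$oncotype)
  mp <- score_template_correlation(expr, definitions$mammaprint)
  data.frame(sample_id = expr$sample_ids,
             proliferation = unname(prolif),
             ror = unname(ror),
             oncotype_rs = onc$score,
             oncotype_risk = onc$risk,
             mammaprint_index = mp$index,
             mammaprint_high_risk = mp$high_risk,
             row.names = NULL, stringsAsFactors = FALSE)
}
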