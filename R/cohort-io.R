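# Cohort merging, normalization, nonnegativity preparation, PAM50
# nearest-centroid assignment, and subtype exclusion filters.

#' Merge cohorts on their shared genes
#'
#' Restricts every cohort to the intersection of gene sets (sorted order),
#' optionally z-scores each gene within each cohort (centering out the
#' location/scale batch differences between platforms), and concatenates
#' the samples, preserving cohort tags. Genes with zero within-cohort
#' variance cannot be z-scored and are dropped, with a message reporting
#' the count.
#'
#' @param bundles List of >= 2 \code{cohort_bundle}s (or bare
#'   \code{expr_matrix} objects).
#' @param normalization \code{"zscore"} (default) or \code{"none"}.
#' @return A merged \code{cohort_bundle}: expression over the shared genes,
#'   concatenated labels/clinical where available, \code{cohort_id}
#'   \code{"merged"}. Ground truths are concatenated when every input
#'   carries one.
#' @export
merge_cohorts <- function(bundles, normalization = c("zscore", "none")) {
  normalization <- match.arg(normalization)
  if (length(bundles) < 2L) stop("need at least two cohorts to merge")
  exprs <- lapply(bundles, function(b)
    if (inherits(b, "cohort_bundle")) b$expression else b)
  if (any(!vapply(exprs, inherits, TRUE, "expr_matrix")))
    stop("each bundle must contain an expr_matrix")
  if (any(vapply(exprs, function(e) ncol(e$values) == 0L, TRUE)))
    stop("empty expression matrix in merge input")
  shared <- Reduce(intersect, lapply(exprs, `[[`, "gene_ids"))
  if (length(shared) == 0L) stop("merge error: empty gene intersection")
  shared <- sort(shared)
  dropped <- character(0)
  mats <- lapply(exprs, function(e) {
    v <- e$values[shared, , drop = FALSE]
    if (normalization == "zscore") {
      mu <- rowMeans(v)
      sdv <- apply(v, 1L, stats::sd)
      dropped <<- union(dropped, shared[sdv == 0])
      v <- (v - mu) / ifelse(sdv == 0, 1, sdv)
    }
    v
  })
  if (length(dropped) > 0L) {
    message(length(dropped), " gene(s) with zero within-cohort variance dropped")
    keep <- setdiff(shared, dropped)
    if (length(keep) == 0L) stop("merge error: no genes left after variance filter")
    mats <- lapply(mats, function(v) v[keep, , drop = FALSE])
    shared <- keep
  }
  values <- do.call(cbind, mats)
  cohort <- unlist(lapply(exprs, `[[`, "cohort"), use.names = FALSE)
  sample_ids <- unlist(lapply(exprs, `[[`, "sample_ids"), use.names = FALSE)
  merged_expr <- expr_matrix(values, gene_ids = shared,
                             sample_ids = sample_ids, cohort = cohort)
  labels <- NULL
  if (all(vapply(bundles, function(b)
    inherits(b, "cohort_bundle") && !is.null(b$labels), TRUE))) {
    labels <- factor(unlist(lapply(bundles, function(b) as.character(b$labels))),
                     levels = levels(bundles[[1L]]$labels))
  }
  clinical <- NULL
  if (all(vapply(bundles, function(b)
    inherits(b, "cohort_bundle") && !is.null(b$clinical), TRUE))) {
    clinical <- do.call(rbind, lapply(bundles, function(b)
      as.data.frame(b$clinical)))
    clinical <- validate_clinical(clinical, where = "merged clinical table")
  }
  truth <- NULL
  truths <- lapply(bundles, function(b)
    if (inherits(b, "cohort_bundle")) b$truth else NULL)
  if (all(!vapply(truths, is.null, TRUE))) {
    truth <- truths[[1L]]
    truth$true_proportions <- do.call(cbind, lapply(truths, `[[`,
                                                    "true_proportions"))
  }
  structure(list(expression = merged_expr, labels = labels,
                 onehot = if (!is.null(labels) &&
                              all(labels %in% SUBTYPES4)) onehot_matrix(labels),
                 clinical = clinical, cohort_id = "merged", truth = truth),
            class = "cohort_bundle")
}

#' Shift each gene to a zero minimum
#'
#' Nonnegative factorization requires a nonnegative input; normalized
#' (z-scored) expression is not. Each gene row is shifted by subtracting its
#' minimum, which preserves all within-row differences exactly. The shift
#' vector is retained in \code{$shift} for provenance.
#'
#' @param expr An \code{expr_matrix}.
#' @return The shifted \code{expr_matrix} (row minima exactly 0).
#' @export
prepare_nonnegative <- function(expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  mins <- apply(expr$values, 1L, min)
  expr$values <- expr$values - mins
  expr$shift <- mins
  expr
}

#' Read a PAM50 centroid table
#'
#' A TSV with a \code{gene} column and one numeric column per subtype
#' (50 rows, unique genes). Lines starting with \code{#} are treated as a
#' provenance header and skipped.
#'
#' @param path Path to the centroid TSV; default is the packaged synthetic
#'   fixture (see \code{\link{pam50_centroid_fixture}}).
#' @param correlation_kind \code{"spearman"} (default, robust to monotone
#'   platform distortions) or \code{"pearson"}.
#' @return An object of class \code{pam50_centroids}: list with
#'   \code{genes}, \code{centroid_matrix} (genes x subtypes),
#'   \code{correlation_kind}.
#' @export
read_centroids <- function(path = pam50_centroid_fixture(),
                           correlation_kind = c("spearman", "pearson")) {
  correlation_kind <- match.arg(correlation_kind)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", check.names = FALSE)
  if (!"gene" %in% names(df)) stop("centroid file needs a 'gene' column")
  genes <- as.character(df$gene)
  if (anyDuplicated(genes)) stop("duplicated genes in centroid file")
  mat <- as.matrix(df[, setdiff(names(df), "gene"), drop = FALSE])
  rownames(mat) <- genes
  if (nrow(mat) != 50L)
    stop("centroid file must contain exactly 50 gene rows, got ", nrow(mat))
  pam50_centroids(mat, correlation_kind)
}

#' Construct a centroid object from a matrix
#'
#' @param centroid_matrix Genes x subtypes numeric matrix with gene row
#'   names and subtype column names.
#' @param correlation_kind \code{"spearman"} or \code{"pearson"}.
#' @return A \code{pam50_centroids} object.
#' @export
pam50_centroids <- function(centroid_matrix,
                            correlation_kind = c("spearman", "pearson")) {
  correlation_kind <- match.arg(correlation_kind)
  if (is.null(rownames(centroid_matrix)) || is.null(colnames(centroid_matrix)))
    stop("centroid matrix needs gene row names and subtype column names")
  structure(list(genes = rownames(centroid_matrix),
                 centroid_matrix = centroid_matrix,
                 correlation_kind = correlation_kind),
            class = "pam50_centroids")
}

#' Path to the packaged synthetic PAM50 centroid fixture
#'
#' The fixture carries the canonical 50 PAM50 gene symbols with synthetic
#' centroid values structured after the subtypes' known expression biology
#' (luminal ESR1/FOXA1 axis, HER2 amplicon, basal keratins, proliferation
#' cluster). It is a stand-in for demonstration and testing, not the
#' published centroid values; supply your own table via
#' \code{\link{read_centroids}} for real analyses.
#'
#' @return File path of the installed fixture.
#' @export
pam50_centroid_fixture <- function() {
  system.file("extdata", "pam50_centroids_synthetic.tsv",
              package = "subtypeAdmix", mustWork = TRUE)
}

#' Estimate per-subtype mean-profile centroids from labeled data
#'
#' @param expr An \code{expr_matrix}.
#' @param labels Per-sample subtype calls (factor/character).
#' @param genes Optional gene subset (default: all genes in \code{expr}).
#' @param correlation_kind Correlation used downstream.
#' @return A \code{pam50_centroids} object with one column per observed
#'   subtype level, in \code{SUBTYPES4} order where applicable.
#' @export
estimate_centroids <- function(expr, labels, genes = expr$gene_ids,
                               correlation_kind = c("spearman", "pearson")) {
  correlation_kind <- match.arg(correlation_kind)
  labels <- as.character(labels)
  lev <- intersect(c(SUBTYPES4, "Normal", "ClaudinLow"), unique(labels))
  v <- expr$values[genes, , drop = FALSE]
  cm <- vapply(lev, function(s) rowMeans(v[, labels == s, drop = FALSE]),
               numeric(length(genes)))
  rownames(cm) <- genes
  pam50_centroids(cm, correlation_kind)
}

#' Assign intrinsic subtypes by nearest-centroid correlation
#'
#' Each sample is assigned the subtype whose centroid maximizes the
#' configured correlation over the genes shared between the expression
#' matrix and the centroid table. At least 25 of the 50 centroid genes must
#' be measured. Ties are broken by a fixed subtype order (LumA, LumB, HER2,
#' Basal, Normal, then any further columns), so calls are deterministic.
#'
#' @param expr An \code{expr_matrix}.
#' @param centroids A \code{pam50_centroids} object.
#' @param min_genes Minimum shared centroid genes (default 25).
#' @return A list of class \code{subtype_labels}: \code{call} (factor),
#'   \code{correlations} (subtype x sample matrix, retained for DRC/ROR
#'   reuse), \code{onehot} (4 x n over the four modeled subtypes, columns
#'   for samples called among them).
#' @export
assign_pam50 <- function(expr, centroids, min_genes = 25L) {
  stopifnot(inherits(expr, "expr_matrix"), inherits(centroids, "pam50_centroids"))
  shared <- intersect(centroids$genes, expr$gene_ids)
  if (length(shared) < min_genes)
    stop("coverage error: only ", length(shared),
         " of the centroid genes are measured (need >= ", min_genes, ")")
  sub_order <- c(SUBTYPES4, "Normal", "ClaudinLow")
  cols <- colnames(centroids$centroid_matrix)
  cols <- c(intersect(sub_order, cols), setdiff(cols, sub_order))
  cm <- centroids$centroid_matrix[shared, cols, drop = FALSE]
  v <- expr$values[shared, , drop = FALSE]
  cors <- suppressWarnings(
    stats::cor(v, cm, method = centroids$correlation_kind))
  cors[is.na(cors)] <- -Inf   # zero-variance sample: every subtype ties
  # max.col(..., "first") honors the fixed-order tie-break
  idx <- max.col(cors, ties.method = "first")
  call <- factor(cols[idx], levels = union(SUBTYPES_ALL, cols))
  names(call) <- expr$sample_ids
  corm <- t(cors)
  corm[!is.finite(corm)] <- NA_real_
  modeled <- call %in% SUBTYPES4
  structure(list(call = call,
                 correlations = corm,
                 onehot = if (any(modeled))
                   onehot_matrix(call[modeled]) else NULL),
            class = "subtype_labels")
}

#' Drop Normal (all cohorts) and Claudin-low (METABRIC-like cohorts) cases
#'
#' Normal-like calls are removed from every cohort; Claudin-low calls are
#' removed only from cohorts flagged METABRIC-like, mirroring the exclusion
#' convention of the source cohorts. The one-hot matrix is rebuilt for the
#' survivors and the removed counts are reported.
#'
#' @param bundle A \code{cohort_bundle} with \code{labels} assigned.
#' @param metabric_like Character vector of cohort tags to which the
#'   Claudin-low exclusion applies (default: tags containing
#'   \code{"metabric"}, case-insensitive).
#' @return The filtered \code{cohort_bundle}.
#' @export
filter_subtypes <- function(bundle,
                            metabric_like = grep("metabric",
                                                 unique(bundle$expression$cohort),
                                                 ignore.case = TRUE, value = TRUE)) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  if (is.null(bundle$labels)) stop("labels must be assigned before filtering")
  lab <- as.character(bundle$labels)
  cohort <- bundle$expression$cohort
  drop <- lab == "Normal" |
    (lab == "ClaudinLow" & cohort %in% metabric_like)
  if (all(drop)) stop("empty cohort: every sample excluded")
  if (any(drop))
    message(sum(lab == "Normal" & drop), " Normal and ",
            sum(lab == "ClaudinLow" & drop), " Claudin-low case(s) removed")
  keep <- !drop
  bundle$expression$values <- bundle$expression$values[, keep, drop = FALSE]
  bundle$expression$sample_ids <- bundle$expression$sample_ids[keep]
  bundle$expression$cohort <- bundle$expression$cohort[keep]
  bundle$labels <- factor(lab[keep], levels = levels(bundle$labels))
  bundle$onehot <- if (all(lab[keep] %in% SUBTYPES4))
    onehot_matrix(bundle$labels) else NULL
  if (!is.null(bundle$clinical)) {
    cl <- as.data.frame(bundle$clinical)
    cl <- cl[match(bundle$expression$sample_ids, cl$sample_id), , drop = FALSE]
    bundle$clinical <- validate_clinical(cl, where = "filtered clinical table")
  }
  if (!is.null(bundle$truth) && !is.null(bundle$truth$true_proportions))
    bundle$truth$true_proportions <-
      bundle$truth$true_proportions[, keep, drop = FALSE]
  bundle
}
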