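SUBTYPES4 <- c("LumA", "LumB", "HER2", "Basal")
SUBTYPES_ALL <- c("LumA", "LumB", "HER2", "Basal", "Normal", "ClaudinLow")

#' Construct a gene-by-sample expression matrix
#'
#' A light container for an m-gene by n-sample expression matrix with
#' identifier bookkeeping and a per-sample cohort tag. All downstream stages
#' (merging, PAM50 assignment, factorization) operate on this class.
#'
#' @param values Numeric matrix, genes in rows, samples in columns. All
#'   entries must be finite.
#' @param gene_ids Character vector of unique gene identifiers (row names).
#' @param sample_ids Character vector of unique sample identifiers.
#' @param cohort Character scalar or per-sample character vector tagging the
#'   cohort of origin.
#' @return An object of class \code{expr_matrix}: a list with elements
#'   \code{values}, \code{gene_ids}, \code{sample_ids}, \code{cohort}, and
#'   \code{shift} (per-gene offsets recorded by \code{\link{prepare_nonnegative}},
#'   initially \code{NULL}).
#' @export
expr_matrix <- function(values, gene_ids = rownames(values),
                        sample_ids = colnames(values), cohort = "cohort1") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("gene_ids and sample_ids are required (or set dimnames on 'values')")
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values))
    stop("gene_ids length does not match row count")
  if (length(sample_ids) != ncol(values))
    stop("sample_ids length does not match column count")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene identifiers: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (any(!is.finite(values)))
    stop("expression matrix contains missing or non-finite values")
  if (length(cohort) == 1L) cohort <- rep(cohort, ncol(values))
  if (length(cohort) != ncol(values))
    stop("cohort tag length does not match sample count")
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(list(values = values, gene_ids = gene_ids,
                 sample_ids = sample_ids, cohort = as.character(cohort),
                 shift = NULL),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s: %d", names(table(x$cohort)),
                            as.integer(table(x$cohort))), collapse = ", ")))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Read a gene-by-sample expression TSV
#'
#' Expects a header row of sample identifiers, a first column of gene
#' identifiers, and numeric cells. Duplicate gene rows and non-numeric cells
#' are format errors.
#'
#' @param path Path to a tab-separated file.
#' @param cohort Cohort tag applied to every sample in the file.
#' @return An \code{\link{expr_matrix}}.
#' @export
read_expression <- function(path, cohort = "cohort1") {
  if (!file.exists(path)) stop("expression file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("expression TSV needs a gene column and >= 1 sample")
  gene_ids <- df[[1L]]
  if (anyDuplicated(gene_ids))
    stop("duplicated gene row(s) in ", path, ": ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  vals <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric expression cell at gene '%s', sample '%s'",
                 gene_ids[bad[1L, 1L]], colnames(vals)[bad[1L, 2L]]))
  if (anyNA(num)) stop("missing expression values in ", path)
  expr_matrix(num, gene_ids = gene_ids, sample_ids = colnames(vals),
              cohort = cohort)
}

#' Write an expression matrix as TSV
#'
#' Inverse of \code{\link{read_expression}}: header row of sample ids, first
#' column \code{gene_id}.
#'
#' @param expr An \code{expr_matrix}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_expression <- function(expr, path) {
  stopifnot(inherits(expr, "expr_matrix"))
  df <- data.frame(gene_id = expr$gene_ids, expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Mandatory clinical columns and their types; booleans stored as 0/1/NA.
CLINICAL_BOOL_COLS <- c("node_positive", "size_gt20", "stage_gt1", "er_pos",
                        "pr_pos", "her2_pos", "tnbc", "mut_TP53",
                        "mut_PIK3CA", "mut_CBFB", "os_event")
CLINICAL_NUM_COLS <- c("age", "os_months")

#' Read a per-sample clinical table
#'
#' One row per sample. Mandatory columns: \code{sample_id}, \code{age}
#' (years), the binary covariates \code{node_positive}, \code{size_gt20},
#' \code{stage_gt1}, \code{er_pos}, \code{pr_pos}, \code{her2_pos},
#' \code{tnbc}, \code{mut_TP53}, \code{mut_PIK3CA}, \code{mut_CBFB}
#' (0/1, may be NA), and right-censored overall survival \code{os_months}
#' (months, >= 0) with \code{os_event} (1 = death observed). Extra columns
#' (e.g. \code{grade}, \code{intclust}) pass through untouched.
#'
#' @param path Path to a tab-separated file.
#' @return A \code{data.frame} of class \code{clinical_table}.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("clinical file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  validate_clinical(df, where = path)
}

validate_clinical <- function(df, where = "clinical table") {
  need <- c("sample_id", CLINICAL_NUM_COLS, CLINICAL_BOOL_COLS)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L)
    stop("missing mandatory clinical column(s) in ", where, ": ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in ", where)
  for (cc in CLINICAL_NUM_COLS) df[[cc]] <- as.numeric(df[[cc]])
  for (cc in CLINICAL_BOOL_COLS) {
    v <- df[[cc]]
    if (is.logical(v)) v <- as.integer(v)
    v <- as.numeric(v)
    if (any(!v %in% c(0, 1) & !is.na(v)))
      stop("clinical column '", cc, "' must be 0/1/NA in ", where)
    df[[cc]] <- as.integer(v)
  }
  if (any(df$os_months < 0, na.rm = TRUE))
    stop("negative survival time in ", where)
  if (anyNA(df$os_months) || anyNA(df$os_event))
    stop("survival time/event may not be missing in ", where)
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Write a clinical table as TSV
#' @param clinical A \code{clinical_table} (or compatible data.frame).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.table(as.data.frame(clinical), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
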