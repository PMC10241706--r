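# Purity metrics derived from the fitted factorization: normalized subtype
# proportions, Shannon entropy, rank-based quartile strata, exclusive
# top-quartile (eQ4) subsets, and the Mahalanobis distance-ratio comparator.

#' Subtype admixture proportions from a fitted model
#'
#' The label reconstruction \code{B S} is interpreted as unnormalized
#' subtype proportion estimates; each column is divided by its sum so the
#' four components (pLumA, pLumB, pHER2, pBasal) sum to one.
#'
#' @param model A fitted \code{ssnmf_model}.
#' @param S_cols Optional coefficient matrix to score (default: the
#'   training \code{model$S}).
#' @param sample_ids Optional column names for the result.
#' @return A 4 x n matrix with rows \code{LumA}, \code{LumB}, \code{HER2},
#'   \code{Basal}; columns sum to 1.
#' @export
admixture_proportions <- function(model, S_cols = model$S,
                                  sample_ids = colnames(S_cols)) {
  BS <- model$B %*% as.matrix(S_cols)
  sums <- colSums(BS)
  bad <- which(sums <= 1e-12)
  if (length(bad) > 0L) {
    nm <- if (!is.null(sample_ids)) sample_ids[bad[1L]] else bad[1L]
    stop("degenerate sample: label reconstruction sums to zero for '", nm, "'")
  }
  P <- sweep(BS, 2L, sums, "/")
  rownames(P) <- SUBTYPES4
  colnames(P) <- sample_ids
  P
}

#' Shannon entropy of a proportion vector, in bits
#'
#' \code{-sum(p * log2(p))} with the convention \code{0 * log 0 = 0}. For a
#' 4-component admixture the entropy lies in [0, 2]: 0 at a pure (one-hot)
#' sample, 2 at the uniform mixture.
#'
#' @param p Nonnegative vector summing to 1 (tolerance 1e-6), or a matrix
#'   whose columns are such vectors.
#' @return Entropy in bits (vector for matrix input).
#' @export
shannon_entropy <- function(p) {
  if (is.matrix(p)) return(apply(p, 2L, shannon_entropy))
  if (any(p < 0)) stop("proportions must be nonnegative")
  if (abs(sum(p) - 1) > 1e-6) stop("proportions must sum to 1")
  nz <- p > 0
  -sum(p[nz] * log2(p[nz]))
}

#' Rank-based quartile strata
#'
#' Samples are ranked ascending (ties broken by stable input order) and the
#' ranks are cut into four contiguous groups with sizes as equal as
#' possible; when n is not divisible by 4 the remainders go to the
#' lowest-numbered quartiles (n = 10 gives sizes 3, 3, 2, 2). Quartile 1
#' holds the smallest values, quartile 4 the largest.
#'
#' @param values Numeric vector, length >= 4.
#' @param groups Number of strata (default 4; use 3 for tertiles).
#' @return Integer vector of strata 1..groups, aligned with \code{values}.
#' @export
quartile_stratify <- function(values, groups = 4L) {
  n <- length(values)
  if (n < groups) stop("need at least ", groups, " samples to stratify")
  ord <- order(values)                        # stable for ties
  base <- n %/% groups
  sizes <- rep(base, groups)
  extra <- n %% groups
  if (extra > 0L) sizes[seq_len(extra)] <- base + 1L
  strata <- integer(n)
  strata[ord] <- rep(seq_len(groups), times = sizes)
  strata
}

#' Exclusive top-quartile (eQ4) subtype assignment
#'
#' For each subtype, samples in the top quartile of that subtype's
#' proportion are flagged; a sample's eQ4 subtype is the one for which it
#' is top-quartile exclusively — top-quartile for that subtype and for no
#' other. Samples top-quartile for zero or for multiple subtypes get
#' \code{"none"}. The four eQ4 sets are pairwise disjoint by construction.
#'
#' @param proportions 4 x n matrix, rows named by subtype.
#' @return A list: \code{eq4} (factor over LumA, LumB, HER2, Basal, none),
#'   \code{top_quartile} (4 x n logical matrix of per-subtype top-quartile
#'   flags).
#' @export
exclusive_top_quartile <- function(proportions) {
  stopifnot(is.matrix(proportions), nrow(proportions) == 4L)
  if (is.null(rownames(proportions))) rownames(proportions) <- SUBTYPES4
  topq <- t(apply(proportions, 1L, function(v) quartile_stratify(v) == 4L))
  count <- colSums(topq)
  eq4 <- rep("none", ncol(proportions))
  only <- count == 1L
  eq4[only] <- rownames(proportions)[apply(topq[, only, drop = FALSE], 2L,
                                           which.max)]
  list(eq4 = factor(eq4, levels = c(SUBTYPES4, "none")),
       top_quartile = topq)
}

#' Pooled within-class covariance with ridge shrinkage
#'
#' Pools the within-subtype covariance of the supplied profiles and shrinks
#' it toward its diagonal: \code{(1 - gamma) * Sigma + gamma * diag(Sigma)}.
#' At PAM50 dimension (50 genes) and realistic class sizes the raw pooled
#' covariance is ill-conditioned; the ridge keeps the Mahalanobis metric
#' stable.
#'
#' @param X Samples x genes matrix.
#' @param classes Per-sample class labels.
#' @param gamma Shrinkage weight in [0, 1), default 0.1.
#' @return The shrunk covariance matrix.
#' @export
pooled_covariance <- function(X, classes, gamma = 0.1) {
  X <- as.matrix(X)
  classes <- as.character(classes)
  p <- ncol(X)
  Sw <- matrix(0, p, p)
  dof <- 0L
  for (cl in unique(classes)) {
    Xi <- X[classes == cl, , drop = FALSE]
    if (nrow(Xi) < 2L) next
    Sw <- Sw + crossprod(scale(Xi, center = TRUE, scale = FALSE))
    dof <- dof + nrow(Xi) - 1L
  }
  if (dof == 0L) stop("no class with >= 2 samples")
  Sw <- Sw / dof
  (1 - gamma) * Sw + gamma * diag(diag(Sw), p)
}

#' Distance Ratio Criteria (DRC)
#'
#' The Mahalanobis distance of a profile from its assigned subtype centroid
#' divided by its distance from the nearest alternate subtype centroid,
#' under a shared covariance. Small values indicate a pure case (close to
#' its own centroid relative to the alternatives); values near or above 1
#' indicate heavy admixture.
#'
#' @param x Numeric profile over the classifier genes.
#' @param centroids Genes x subtypes matrix of per-subtype mean profiles
#'   (or a \code{pam50_centroids} object).
#' @param covariance Shared positive-definite covariance (e.g. from
#'   \code{\link{pooled_covariance}}).
#' @param assigned Name (or index) of the assigned subtype column.
#' @return The nonnegative distance ratio.
#' @export
distance_ratio_criteria <- function(x, centroids, covariance, assigned) {
  if (inherits(centroids, "pam50_centroids"))
    centroids <- centroids$centroid_matrix
  R <- tryCatch(chol(covariance),
                error = function(e) stop("covariance is not positive definite ",
                                         "after shrinkage: ", conditionMessage(e)))
  d2 <- apply(centroids, 2L, function(mu) {
    z <- backsolve(R, x - mu, transpose = TRUE)
    sum(z^2)
  })
  if (is.character(assigned)) assigned <- match(assigned, colnames(centroids))
  if (is.na(assigned) || assigned < 1L || assigned > length(d2))
    stop("assigned subtype not found among the centroids")
  d_own <- sqrt(d2[assigned])
  d_alt <- sqrt(min(d2[-assigned]))
  if (d_alt == 0) {
    if (d_own == 0) return(0)
    stop("degenerate instance: zero distance to an alternate centroid")
  }
  unname(d_own / d_alt)
}

#' Equal-width histogram of proportion values
#'
#' The value range is divided into \code{bins} equally spaced intervals
#' (left-closed, right-open, with the last bin right-closed), matching the
#' convention used for the per-subtype proportion frequency plots. Counts
#' always sum to the number of values.
#'
#' @param values Numeric vector (n >= 1).
#' @param bins Number of intervals (default 100).
#' @return A data.frame with \code{bin_left}, \code{bin_right},
#'   \code{count}, plus attribute \code{degenerate = TRUE} when every value
#'   is identical (single collapsed bin).
#' @export
proportion_histogram <- function(values, bins = 100L) {
  if (length(values) < 1L) stop("need at least one value")
  lo <- min(values); hi <- max(values)
  if (lo == hi) {
    out <- data.frame(bin_left = lo, bin_right = hi, count = length(values))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  edges <- seq(lo, hi, length.out = bins + 1L)
  width <- (hi - lo) / bins
  idx <- pmin(bins, floor((values - lo) / width) + 1L)
  counts <- tabulate(idx, nbins = bins)
  out <- data.frame(bin_left = edges[-(bins + 1L)], bin_right = edges[-1L],
                    count = counts)
  attr(out, "degenerate") <- FALSE
  out
}

#' Assemble the per-sample admixture table
#'
#' Combines proportions, entropy, purity quartile (by pLumA; quartile 4 =
#' purest), eQ4 subtype and (optionally) DRC into the tidy per-sample table
#' that downstream comparisons and exports consume.
#'
#' @param proportions 4 x n matrix from
#'   \code{\link{admixture_proportions}}.
#' @param sample_ids Sample identifiers (default: column names).
#' @param cohort Optional per-sample cohort tags.
#' @param drc Optional per-sample DRC values.
#' @return A data.frame: sample_id, cohort, pLumA..pBasal, entropy_bits,
#'   drc, purity_quartile, eq4_subtype.
#' @export
admixture_table <- function(proportions, sample_ids = colnames(proportions),
                            cohort = NULL, drc = NULL) {
  n <- ncol(proportions)
  if (is.null(sample_ids)) sample_ids <- sprintf("s%04d", seq_len(n))
  eq <- exclusive_top_quartile(proportions)
  data.frame(sample_id = sample_ids,
             cohort = if (is.null(cohort)) NA_character_ else cohort,
             pLumA = proportions["LumA", ],
             pLumB = proportions["LumB", ],
             pHER2 = proportions["HER2", ],
             pBasal = proportions["Basal", ],
             entropy_bits = shannon_entropy(proportions),
             drc = if (is.null(drc)) NA_real_ else drc,
             purity_quartile = quartile_stratify(proportions["LumA", ]),
             eq4_subtype = as.character(eq$eq4),
             row.names = NULL, stringsAsFactors = FALSE)
}
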