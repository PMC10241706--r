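# Stratified group comparisons: extreme-stratum tests (Welch t for
# continuous features, Fisher's exact for binary), trend tests across
# ordered strata (Cochran-Armitage for binary, least-squares slope for
# continuous), and cross-classified cell means.

#' Compare features between the extreme strata and test for trend
#'
#' For each feature, summarizes every stratum (mean for continuous,
#' percent positive for binary), tests the lowest versus the highest
#' stratum (two-tailed Welch t-test for continuous, two-sided Fisher's
#' exact test on the 2x2 table for binary), and computes a trend p-value
#' across the ordered strata via \code{\link{trend_test}}. Missing values
#' are dropped per feature (complete-case), with the used counts reported.
#'
#' @param clinical A data.frame (e.g. \code{clinical_table}) holding the
#'   features.
#' @param strata Integer per-sample stratum labels (ordered, 1 = lowest).
#' @param features Character vector of column names to compare.
#' @param kinds Optional named character vector declaring each feature
#'   \code{"continuous"} or \code{"binary"}; by default 0/1 (or logical)
#'   columns are treated as binary, the rest continuous.
#' @return A data.frame, one row per feature: \code{feature}, \code{kind},
#'   per-stratum summaries \code{stratum1..} (mean or percent),
#'   \code{p_extreme}, \code{p_trend}, \code{test_used}, per-stratum
#'   \code{n1..}. Features degenerate in either extreme stratum are
#'   skipped with a warning.
#' @export
compare_groups <- function(clinical, strata, features, kinds = NULL) {
  strata <- as.integer(strata)
  levs <- sort(unique(strata))
  if (length(levs) < 2L) stop("need at least two strata")
  lo <- levs[1L]; hi <- levs[length(levs)]
  rows <- list()
  for (feat in features) {
    v <- clinical[[feat]]
    if (is.null(v)) stop("feature not found: ", feat)
    if (is.logical(v)) v <- as.integer(v)
    kind <- if (!is.null(kinds) && feat %in% names(kinds)) kinds[[feat]]
            else if (all(v %in% c(0L, 1L) | is.na(v))) "binary" else "continuous"
    ok <- !is.na(v)
    if (sum(ok & strata == lo) == 0L || sum(ok & strata == hi) == 0L) {
      warning("feature '", feat, "' empty in an extreme stratum; skipped",
              call. = FALSE)
      next
    }
    summ <- vapply(levs, function(s) {
      vs <- v[ok & strata == s]
      if (length(vs) == 0L) return(NA_real_)
      if (kind == "binary") 100 * mean(vs) else mean(vs)
    }, numeric(1L))
    ns <- vapply(levs, function(s) sum(ok & strata == s), integer(1L))
    v_lo <- v[ok & strata == lo]; v_hi <- v[ok & strata == hi]
    if (kind == "binary") {
      tab <- rbind(c(sum(v_lo == 1L), sum(v_lo == 0L)),
                   c(sum(v_hi == 1L), sum(v_hi == 0L)))
      p_ext <- stats::fisher.test(tab, alternative = "two.sided")$p.value
      test_used <- "fisher_exact"
    } else if (stats::sd(v_lo) == 0 && stats::sd(v_hi) == 0) {
      p_ext <- if (mean(v_lo) == mean(v_hi)) 1 else NA_real_
      test_used <- "degenerate_constant"
    } else {
      p_ext <- stats::t.test(v_lo, v_hi, alternative = "two.sided")$p.value
      test_used <- "welch_t"
    }
    p_tr <- trend_test(v[ok], strata[ok], kind = kind)
    row <- data.frame(feature = feat, kind = kind, t(summ), p_extreme = p_ext,
                      p_trend = p_tr, test_used = test_used, t(ns),
                      stringsAsFactors = FALSE)
    names(row)[3:(2 + length(levs))] <- paste0("stratum", levs)
    names(row)[(ncol(row) - length(levs) + 1L):ncol(row)] <- paste0("n", levs)
    rows[[feat]] <- row
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Trend test across ordered strata
#'
#' Binary features: Cochran-Armitage trend test with integer scores over
#' the ordered strata (\code{stats::prop.trend.test}). Continuous
#' features: two-sided p-value of the slope from a least-squares
#' regression of the feature on the stratum score. Returns \code{NA} when
#' fewer than three strata are non-degenerate.
#'
#' @param values Feature values (no NAs).
#' @param strata Ordered integer strata.
#' @param kind \code{"binary"} or \code{"continuous"}.
#' @return The trend p-value, or NA when undefined.
#' @export
trend_test <- function(values, strata, kind = c("binary", "continuous")) {
  kind <- match.arg(kind)
  strata <- as.integer(strata)
  levs <- sort(unique(strata))
  if (length(levs) < 3L) return(NA_real_)
  if (kind == "binary") {
    x <- vapply(levs, function(s) sum(values[strata == s] == 1L), numeric(1L))
    n <- vapply(levs, function(s) sum(strata == s), numeric(1L))
    if (sum(x) == 0 || sum(x) == sum(n)) return(NA_real_)
    suppressWarnings(stats::prop.trend.test(x, n, score = levs)$p.value)
  } else {
    if (stats::sd(values) == 0) return(NA_real_)
    fit <- stats::lm(values ~ strata)
    co <- summary(fit)$coefficients
    if (nrow(co) < 2L) return(NA_real_)
    co["strata", "Pr(>|t|)"]
  }
}

#' Cross-classified cell means
#'
#' Mean of a per-sample value in every cell of the strataA x strataB grid
#' (e.g. mean EGFR expression by pLumA quartile crossed with pBasal
#' quartile). Empty cells are NA.
#'
#' @param values Per-sample numeric vector.
#' @param strataA,strataB Integer strata defined on the same samples.
#' @return A list: \code{means} (A x B matrix), \code{counts}
#'   (same shape; counts sum to the number of samples).
#' @export
cross_classified_means <- function(values, strataA, strataB) {
  if (length(values) != length(strataA) || length(values) != length(strataB))
    stop("values and strata must align")
  la <- sort(unique(strataA)); lb <- sort(unique(strataB))
  means <- matrix(NA_real_, length(la), length(lb),
                  dimnames = list(paste0("A", la), paste0("B", lb)))
  counts <- matrix(0L, length(la), length(lb), dimnames = dimnames(means))
  for (i in seq_along(la)) for (j in seq_along(lb)) {
    sel <- strataA == la[i] & strataB == lb[j]
    counts[i, j] <- sum(sel)
    if (any(sel)) means[i, j] <- mean(values[sel])
  }
  list(means = means, counts = counts)
}
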