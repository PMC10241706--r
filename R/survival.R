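# Survival stage: Kaplan-Meier estimation with Greenwood CIs, log-rank
# comparison, and unadjusted / adjusted Cox proportional-hazards models
# with the purest stratum as referent. All fitting is delegated to the
# survival package; this layer fixes the conventions (Efron ties, referent
# choice, median definition) and returns tidy structures.

#' Kaplan-Meier fit per group
#'
#' Product-limit estimate per group with Greenwood-based confidence
#' intervals (log transform, the survival-package default), the median
#' (earliest time at which survival drops to 0.5 or below; NA when never
#' reached), survival probabilities read from the step function at
#' requested times, and the log-rank test across groups.
#'
#' @param os_months Nonnegative follow-up times (months).
#' @param os_event Event indicator (1 = death observed).
#' @param groups Per-sample group labels (each group non-empty).
#' @param survival_at Times (months) at which to read survival
#'   probabilities (default 120, i.e. 10-year survival).
#' @param conf_level Confidence level (default 0.95).
#' @return A list of class \code{km_fit}: \code{curves} (data.frame:
#'   group, time, n_risk, n_event, survival, ci_low, ci_high),
#'   \code{median_months} (named), \code{survival_at} (data.frame: group,
#'   months, survival, ci_low, ci_high), \code{logrank_p}, \code{n},
#'   \code{events}.
#' @export
km_fit <- function(os_months, os_event, groups,
                   survival_at = 120, conf_level = 0.95) {
  if (any(os_months < 0)) stop("negative survival time")
  groups <- factor(groups)
  if (any(table(groups) == 0L)) stop("empty group")
  df <- data.frame(time = os_months, event = as.integer(os_event),
                   group = groups)
  sf <- survival::survfit(survival::Surv(time, event) ~ group, data = df,
                          conf.type = "log", conf.int = conf_level)
  strata_name <- if (is.null(sf$strata)) levels(groups)[1L] else
    sub("^group=", "", names(sf$strata))
  grp <- if (is.null(sf$strata)) rep(strata_name, length(sf$time)) else
    rep(strata_name, sf$strata)
  curves <- data.frame(group = grp, time = sf$time, n_risk = sf$n.risk,
                       n_event = sf$n.event, survival = sf$surv,
                       ci_low = sf$lower, ci_high = sf$upper,
                       stringsAsFactors = FALSE)
  medians <- vapply(levels(groups), function(g) {
    cg <- curves[curves$group == g, ]
    hit <- which(cg$survival <= 0.5)
    if (length(hit) == 0L) NA_real_ else cg$time[hit[1L]]
  }, numeric(1L))
  surv_at <- do.call(rbind, lapply(survival_at, function(tt) {
    sm <- summary(sf, times = tt, extend = TRUE)
    g <- if (is.null(sm$strata)) levels(groups) else
      sub("^group=", "", as.character(sm$strata))
    data.frame(group = g, months = tt, survival = sm$surv,
               ci_low = sm$lower, ci_high = sm$upper,
               stringsAsFactors = FALSE)
  }))
  logrank_p <- NA_real_
  if (nlevels(groups) > 1L) {
    sd0 <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
    logrank_p <- stats::pchisq(sd0$chisq, df = nlevels(groups) - 1L,
                               lower.tail = FALSE)
  }
  structure(list(curves = curves, median_months = medians,
                 survival_at = surv_at, logrank_p = logrank_p,
                 n = nrow(df), events = sum(df$event)),
            class = "km_fit")
}

#' Cox proportional-hazards contrasts against the purest stratum
#'
#' Fits a Cox model (Efron tie correction) with the strata as a factor,
#' using the highest stratum (the purest, when strata are purity
#' quartiles) as the referent, optionally adjusted for covariates.
#' Reports per-contrast hazard ratios with Wald confidence intervals and
#' p-values, plus a trend p across the ordered strata from a score-coded
#' (linear) model with the same adjustment.
#'
#' @param os_months,os_event Survival outcome.
#' @param strata Ordered per-sample strata (integer or ordered factor);
#'   the highest level is the referent.
#' @param covariates Optional data.frame of adjustment covariates
#'   (complete cases enforced; rows dropped are reported via attribute
#'   \code{n_dropped}).
#' @param referent Level used as referent (default: the highest).
#' @return A list of class \code{cox_fit}: \code{contrasts} (data.frame:
#'   level, hr, ci_low, ci_high, p), \code{trend_p}, \code{adjusted_for},
#'   \code{n}, \code{events}, \code{converged}.
#' @export
cox_hr <- function(os_months, os_event, strata, covariates = NULL,
                   referent = NULL) {
  strata <- factor(strata)
  levs <- levels(strata)
  if (is.null(referent)) referent <- levs[length(levs)]
  df <- data.frame(time = os_months, event = as.integer(os_event),
                   stratum = stats::relevel(strata, ref = as.character(referent)),
                   score = as.numeric(factor(strata, levels = levs)))
  adj <- character(0)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    adj <- names(covariates)
    df <- cbind(df, covariates)
  }
  cc <- stats::complete.cases(df)
  n_dropped <- sum(!cc)
  df <- df[cc, , drop = FALSE]
  ev_per_level <- tapply(df$event, df$stratum, sum)
  if (any(is.na(ev_per_level)) || any(ev_per_level < 1))
    stop("every compared stratum needs at least one event")
  rhs <- paste(c("stratum", adj), collapse = " + ")
  fit <- survival::coxph(stats::as.formula(
    paste("survival::Surv(time, event) ~", rhs)), data = df, ties = "efron")
  sm <- summary(fit)
  rows <- grep("^stratum", rownames(sm$coefficients))
  contrasts <- data.frame(
    level = sub("^stratum", "", rownames(sm$coefficients)[rows]),
    hr = sm$coefficients[rows, "exp(coef)"],
    ci_low = sm$conf.int[rows, "lower .95"],
    ci_high = sm$conf.int[rows, "upper .95"],
    p = sm$coefficients[rows, "Pr(>|z|)"],
    row.names = NULL, stringsAsFactors = FALSE)
  rhs_tr <- paste(c("score", adj), collapse = " + ")
  fit_tr <- survival::coxph(stats::as.formula(
    paste("survival::Surv(time, event) ~", rhs_tr)), data = df, ties = "efron")
  trend_p <- summary(fit_tr)$coefficients["score", "Pr(>|z|)"]
  out <- structure(list(contrasts = contrasts, trend_p = trend_p,
                        adjusted_for = adj, n = nrow(df),
                        events = sum(df$event),
                        converged = fit$iter < survival::coxph.control()$iter.max,
                        model = fit),
                   class = "cox_fit")
  attr(out, "n_dropped") <- n_dropped
  out
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox PH (Efron ties): %d subjects, %d events%s\n", x$n, x$events,
              if (length(x$adjusted_for) > 0)
                paste0("; adjusted for ", paste(x$adjusted_for, collapse = ", "))
              else ""))
  print(transform(x$contrasts, hr = round(hr, 3), ci_low = round(ci_low, 3),
                  ci_high = round(ci_high, 3), p = signif(p, 3)))
  cat(sprintf("trend p = %.3g\n", x$trend_p))
  invisible(x)
}
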