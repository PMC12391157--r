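#' Adjusted linear regression of an RV outcome on a baseline predictor
#'
#' Ordinary least squares of `outcome ~ predictor + sex + age_cmr1 +
#' age_cmr2`: each hemodynamic or geometric predictor is tested in its own
#' model adjusted for patient sex and the ages at both scans. The effect
#' estimate is the predictor coefficient (outcome units per predictor unit).
#'
#' @param cohort cohort data.frame (see [make_synthetic_cohort()]).
#' @param outcome name of the outcome column (e.g. `"rvedvi"`).
#' @param predictor name of the predictor column.
#' @param covariates adjustment covariate column names.
#' @return An object of class `linear_fit_result`: `effect_estimate`, `se`,
#'   `unadjusted_p`, `adjusted_p` (NA until multiplicity adjustment), `n`,
#'   plus the underlying `lm` fit.
#' @export
fit_linear_outcome <- function(cohort, outcome, predictor,
                               covariates = c("sex", "age_cmr1", "age_cmr2")) {
  cols <- c(outcome, predictor, covariates)
  missing_cols <- setdiff(cols, names(cohort))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  d <- cohort[complete.cases(cohort[cols]), cols, drop = FALSE]
  if (nrow(d) <= length(cols)) stop("too few rows for the model")
  if (sd(d[[predictor]]) == 0) stop("predictor is constant")
  fm <- stats::reformulate(c(predictor, covariates), response = outcome)
  fit <- lm(fm, data = d)
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("collinear design; aliased terms: ", paste(bad, collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  structure(list(effect_estimate = unname(sm[predictor, 1L]),
                 se = unname(sm[predictor, 2L]),
                 unadjusted_p = unname(sm[predictor, 4L]),
                 adjusted_p = NA_real_, n = nrow(d),
                 outcome = outcome, predictor = predictor, fit = fit),
            class = "linear_fit_result")
}

#' @export
print.linear_fit_result <- function(x, ...) {
  cat(sprintf("<linear_fit_result> %s ~ %s: effect %.4g (SE %.3g), p = %.4g%s\n",
              x$outcome, x$predictor, x$effect_estimate, x$se, x$unadjusted_p,
              if (is.na(x$adjusted_p)) ""
              else sprintf(", BH-adjusted p = %.4g", x$adjusted_p)))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: each adjusted value is
#' `min over j >= i of p_(j) m / j`, capped at 1, returned in the input
#' order.
#'
#' @param pvals numeric p-values in (0, 1].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  pvals <- as.numeric(pvals)
  if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals > 1))
    stop("p-values must lie in (0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Adjusted linear regression across a table of predictors
#'
#' Fits [fit_linear_outcome()] for every predictor against one outcome and
#' applies Benjamini-Hochberg adjustment within that outcome's family (the
#' per-table convention; set `bh_family = "none"` to skip).
#'
#' @param cohort cohort data.frame.
#' @param outcome outcome column name.
#' @param predictors character vector of predictor columns.
#' @param covariates adjustment covariates.
#' @param bh_family `"per_table"` (default) or `"none"`.
#' @return data.frame: `predictor`, `effect_estimate`, `se`,
#'   `unadjusted_p`, `adjusted_p`, `n`.
#' @export
fit_linear_table <- function(cohort, outcome, predictors,
                             covariates = c("sex", "age_cmr1", "age_cmr2"),
                             bh_family = c("per_table", "none")) {
  bh_family <- match.arg(bh_family)
  fits <- lapply(predictors, function(p)
    fit_linear_outcome(cohort, outcome, p, covariates))
  out <- data.frame(
    predictor = predictors,
    effect_estimate = vapply(fits, `[[`, numeric(1), "effect_estimate"),
    se = vapply(fits, `[[`, numeric(1), "se"),
    unadjusted_p = vapply(fits, `[[`, numeric(1), "unadjusted_p"),
    n = vapply(fits, `[[`, numeric(1), "n"))
  out$adjusted_p <- if (bh_family == "per_table")
    bh_adjust(out$unadjusted_p) else NA_real_
  out
}

#' Multivariable Cox proportional hazards fit for one predictor
#'
#' Partial-likelihood fit of `Surv(time, event) ~ predictor + age + sex`
#' with the adjustment covariates chosen a priori. Optionally the predictor
#' is divided by its SD first, so the hazard ratio is per SD increase. The
#' proportional-hazards assumption is checked via the Schoenfeld-residual
#' correlation-with-time test (alpha 0.05); the result is reported, never
#' used to drop variables.
#'
#' @param records survival data.frame with `time_days`, `event`, the
#'   predictor column, and covariates.
#' @param predictor predictor column name.
#' @param normalize divide the predictor by its SD (per-SD hazard ratio).
#' @param covariates adjustment covariate names.
#' @return An object of class `cox_result`: `hazard_ratio`, `ci_low`,
#'   `ci_high`, `p`, `log_hr`, `se`, `schoenfeld_ok`, `schoenfeld_p`,
#'   `normalized`, `separation` (TRUE when a monotone likelihood was
#'   flagged), `n_events`, plus the underlying `coxph` fit.
#' @export
fit_cox <- function(records, predictor, normalize = FALSE,
                    covariates = c("age_cmr", "sex")) {
  cols <- c("time_days", "event", predictor, covariates)
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  d <- records[complete.cases(records[cols]), cols, drop = FALSE]
  if (sum(d$event) < 1L) stop("no events: Cox model cannot be fitted")
  if (sd(d[[predictor]]) == 0) stop("predictor is constant")
  d$.pred <- if (normalize) d[[predictor]] / sd(d[[predictor]])
    else d[[predictor]]
  fm <- stats::reformulate(c(".pred", covariates),
                           response = "survival::Surv(time_days, event)")
  separation <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fm, data = d),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)
  beta <- unname(coef(fit)[".pred"])
  se <- unname(sqrt(diag(vcov(fit)))[1L])
  if (!separation && (abs(beta) > 50 || se > 50)) separation <- TRUE
  zph <- tryCatch(survival::cox.zph(fit), error = function(e) NULL)
  sch_p <- if (is.null(zph)) NA_real_ else unname(zph$table[".pred", "p"])
  structure(list(hazard_ratio = exp(beta),
                 ci_low = exp(beta - 1.96 * se),
                 ci_high = exp(beta + 1.96 * se),
                 p = unname(sm$coefficients[".pred", "Pr(>|z|)"]),
                 log_hr = beta, se = se,
                 schoenfeld_ok = !is.na(sch_p) && sch_p > 0.05,
                 schoenfeld_p = sch_p,
                 normalized = normalize, separation = separation,
                 n_events = sum(d$event), predictor = predictor, fit = fit),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("<cox_result> %s%s: HR %.3g (95%% CI %.3g-%.3g), p = %.4g\n",
              x$predictor, if (x$normalized) " (per SD)" else "",
              x$hazard_ratio, x$ci_low, x$ci_high, x$p))
  if (x$separation) cat("  warning: monotone likelihood / separation flagged\n")
  cat(sprintf("  Schoenfeld PH check: p = %.3g (%s)\n", x$schoenfeld_p,
              if (isTRUE(x$schoenfeld_ok)) "ok" else "violation or NA"))
  invisible(x)
}

#' Dichotomize survival records at the median event time
#'
#' For ROC analysis of "event by the median time-to-event": label 1 if the
#' event occurred at or before the median event time; 0 if the subject was
#' followed to or beyond the median without an event; subjects censored
#' before the median are excluded (NA) since their status at the landmark is
#' unknown.
#'
#' @param records survival data.frame with `time_days` and `event`.
#' @return integer vector of labels (1/0/NA) with attribute `median_time`.
#' @export
dichotomize_by_median_time <- function(records) {
  ev <- records$event == 1
  if (!any(ev)) stop("no events: cannot locate the median event time")
  med <- median(records$time_days[ev])
  labels <- rep(NA_integer_, nrow(records))
  labels[ev & records$time_days <= med] <- 1L
  labels[is.na(labels) & records$time_days >= med] <- 0L
  if (!any(labels == 0L, na.rm = TRUE))
    stop("no subject followed beyond the median event time")
  structure(labels, median_time = med)
}

#' ROC-optimal cutoff maximizing sensitivity + specificity
#'
#' Exhaustive search over all midpoints between adjacent sorted unique
#' scores (plus outer sentinels), in both directions (high scores predict
#' the event, or low scores do). Ties in the criterion resolve to the
#' smallest qualifying cutoff with the `">="` direction preferred.
#'
#' @param scores numeric predictor values.
#' @param labels binary labels (1 = event); NA pairs are dropped.
#' @return list: `cutoff`, `sensitivity`, `specificity`, `direction`
#'   (`">="` means score >= cutoff predicts the event), `criterion`
#'   (sensitivity + specificity).
#' @export
roc_optimal_cutoff <- function(scores, labels) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- as.integer(labels[keep])
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary")
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  u <- sort(unique(scores))
  cuts <- if (length(u) == 1L) u else
    c(u[1L] - 1, (u[-length(u)] + u[-1L]) / 2, u[length(u)] + 1)
  best <- list(criterion = -Inf)
  for (cut in cuts) {
    for (dir in c(">=", "<=")) {
      pred <- if (dir == ">=") scores >= cut else scores <= cut
      sens <- sum(pred & labels == 1L) / sum(labels == 1L)
      spec <- sum(!pred & labels == 0L) / sum(labels == 0L)
      if (sens + spec > best$criterion + 1e-12) {
        best <- list(cutoff = cut, sensitivity = sens, specificity = spec,
                     direction = dir, criterion = sens + spec)
      }
    }
  }
  best
}

#' Kaplan-Meier survival curves by group
#'
#' Product-limit estimates of event-free survival for each group (e.g.
#' above/below a ROC cutoff), via [survival::survfit()].
#'
#' @param records survival data.frame with `time_days`, `event`.
#' @param groups group label per record.
#' @return An object of class `km_curves`: data.frame with `group`, `time`,
#'   `survival`, `n_risk`, `n_event` (right-continuous step functions
#'   starting at 1), plus the underlying `survfit` in attribute `fit`.
#' @export
km_curve <- function(records, groups) {
  groups <- as.factor(groups)
  if (any(table(groups) == 0L)) stop("groups must be non-empty")
  d <- data.frame(time = records$time_days, event = records$event,
                  group = groups)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  if (is.null(fit$strata)) {
    strata <- rep(levels(groups)[1L], length(fit$time))
  } else {
    strata <- rep(sub("^group=", "", names(fit$strata)), fit$strata)
  }
  out <- data.frame(group = strata, time = fit$time, survival = fit$surv,
                    n_risk = fit$n.risk, n_event = fit$n.event)
  structure(out, class = c("km_curves", "data.frame"), fit = fit)
}

#' @export
plot.km_curves <- function(x, xlab = "time (days)",
                           ylab = "event-free survival", ...) {
  groups <- unique(x$group)
  plot(NA, xlim = c(0, max(x$time)), ylim = c(0, 1), xlab = xlab,
       ylab = ylab, ...)
  for (i in seq_along(groups)) {
    d <- x[x$group == groups[i], ]
    lines(stats::stepfun(d$time, c(1, d$survival)), col = i, do.points = FALSE)
  }
  legend("bottomleft", legend = groups, col = seq_along(groups), lty = 1)
  invisible(x)
}
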