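#' Harrell's concordance index
#'
#' Event-anchored pairwise concordance between risk scores and observed
#' times: a pair is usable when the subject with the shorter time had an
#' event (or, at tied times, exactly one of the pair had an event); a usable
#' pair is concordant when the earlier-event subject has the higher risk,
#' and risk ties count 0.5.
#'
#' @param risk numeric risk scores (higher = predicted earlier event).
#' @param surv a `survival_table` (or data.frame with `time`, `event`).
#' @return C-index in \[0, 1\].
#' @export
concordance_index <- function(risk, surv) {
  stopifnot(length(risk) == nrow(surv), all(is.finite(risk)))
  time <- surv$time; event <- surv$event
  n <- length(risk)
  ev <- matrix(event == 1, n, n)
  # usable (i anchors): i's time shorter with event, or tied with j censored
  usable <- (outer(time, time, "<") & ev) |
            (outer(time, time, "==") & ev & t(!ev))
  diag(usable) <- FALSE
  n_usable <- sum(usable)
  if (n_usable == 0) stop("no usable pairs (no anchoring events)")
  conc <- sum(usable & outer(risk, risk, ">")) +
          0.5 * sum(usable & outer(risk, risk, "=="))
  conc / n_usable
}

refit_coxph <- function(features, surv) {
  y <- survival::Surv(surv$time, surv$event)
  if (is.null(features) || NCOL(features) == 0) {
    return(survival::coxph(y ~ 1))
  }
  x <- as.data.frame(features)
  x$id <- NULL
  df <- cbind(data.frame(.time = surv$time, .event = surv$event), x)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", colnames(x)), collapse = " + ")))
  fit <- survival::coxph(fml, data = df)
  if (!is.null(fit$info) && any(grepl("did not converge", fit$info)))
    stop("Cox refit did not converge")
  fit
}

#' AIC of an unpenalised Cox refit
#'
#' Refits a standard (unpenalised) Cox model on the given feature columns
#' and returns `-2 log PL + 2 p`. With zero features this is `-2 log PL` of
#' the null partial likelihood. AIC is undefined for penalised fits, so this
#' refit is the standard route to compare selected supports.
#'
#' @param features data.frame of the selected features (or `NULL` for the
#'   null model).
#' @param surv a `survival_table`.
#' @return AIC (numeric).
#' @export
cox_aic <- function(features, surv) {
  fit <- refit_coxph(features, surv)
  p <- length(stats::coef(fit))
  ll <- if (p == 0) fit$loglik[1] else fit$loglik[2]
  -2 * ll + 2 * p
}

# Kaplan-Meier estimate of the censoring distribution G(u) = P(C > u),
# evaluated as a left-continuous (G(u-)) or right-continuous step function.
censoring_km <- function(surv) {
  survival::survfit(survival::Surv(surv$time, 1 - surv$event) ~ 1)
}

km_surv_at <- function(fit, u, left = FALSE) {
  tt <- fit$time; ss <- fit$surv
  vapply(u, function(ui) {
    sel <- if (left) tt < ui else tt <= ui
    if (!any(sel)) 1.0 else ss[max(which(sel))]
  }, numeric(1))
}

#' Time-dependent AUC with censoring weights
#'
#' Cumulative/dynamic AUC at horizon `t`: cases are subjects with an event
#' by `t`, controls are subjects still at risk after `t`; case weights are
#' inverse Kaplan-Meier censoring probabilities `1/G(T_i-)` (the uniform
#' control weight `1/G(t)` cancels). With no censoring before `t` this
#' reduces to the plain binary AUC of event-by-t against the score.
#'
#' @param risk numeric risk scores.
#' @param surv a `survival_table`.
#' @param t horizon (same units as `surv$time`).
#' @return AUC(t) in \[0, 1\].
#' @export
auc_at_time <- function(risk, surv, t) {
  stopifnot(length(risk) == nrow(surv))
  case <- surv$time <= t & surv$event == 1
  control <- surv$time > t
  if (!any(case)) stop("no events by t = ", t)
  if (!any(control)) stop("no subjects at risk after t = ", t)
  G <- censoring_km(surv)
  w <- 1 / pmax(km_surv_at(G, surv$time[case], left = TRUE), 1e-10)
  rc <- risk[case]; rk <- risk[control]
  wins <- vapply(seq_along(rc), function(i)
    sum(rc[i] > rk) + 0.5 * sum(rc[i] == rk), numeric(1))
  sum(w * wins) / (sum(w) * length(rk))
}

#' Categorical net reclassification improvement at a horizon
#'
#' Two risk categories per model, split at each model's own median. "Up"
#' subjects move low -> high from the old to the new model, "down" the
#' reverse. Event and non-event proportions at horizon `t` are estimated
#' with Kaplan-Meier within each movement group, so subjects censored before
#' `t` contribute through the KM weighting rather than being dropped:
#' `NRI_event = P(up|event) - P(down|event)` and
#' `NRI_nonevent = P(down|nonevent) - P(up|nonevent)`, with
#' `NRI = NRI_event + NRI_nonevent`. The confidence interval and p-value
#' come from a seeded subject-level bootstrap (medians recomputed per
#' resample).
#'
#' @param risk_old,risk_new risk scores of the two models on the same
#'   subjects.
#' @param surv a `survival_table`.
#' @param t horizon; must be within follow-up.
#' @param B bootstrap replicates (0 skips the CI).
#' @param seed integer seed for the bootstrap.
#' @param conf_level CI level.
#' @return An `nri_record`: `nri`, `nri_event`, `nri_nonevent`, `ci`, `p`,
#'   `table` (reclassification counts by event status at `t`).
#' @export
nri_categorical <- function(risk_old, risk_new, surv, t, B = 1000,
                            seed = NULL, conf_level = 0.95) {
  stopifnot(length(risk_old) == nrow(surv),
            length(risk_new) == nrow(surv))
  if (t > max(surv$time)) stop("horizon t = ", t, " is beyond follow-up")

  point <- nri_point(risk_old, risk_new, surv, t)

  old_high <- risk_old > stats::median(risk_old)
  new_high <- risk_new > stats::median(risk_new)
  status <- ifelse(surv$time <= t & surv$event == 1, "event",
                   ifelse(surv$time > t, "nonevent", "censored_before_t"))
  tab <- table(old = factor(old_high, c(FALSE, TRUE), c("low", "high")),
               new = factor(new_high, c(FALSE, TRUE), c("low", "high")),
               status = status)

  ci <- c(NA_real_, NA_real_); pval <- NA_real_
  if (B > 0) {
    set_seed_if(seed)
    n <- nrow(surv)
    boot <- vapply(seq_len(B), function(b) {
      j <- sample.int(n, n, replace = TRUE)
      tryCatch(nri_point(risk_old[j], risk_new[j], surv[j, ], t)["nri"],
               error = function(e) NA_real_)
    }, numeric(1))
    boot <- boot[is.finite(boot)]
    alpha <- 1 - conf_level
    ci <- unname(stats::quantile(boot, c(alpha / 2, 1 - alpha / 2)))
    se <- stats::sd(boot)
    pval <- if (se > 0) 2 * stats::pnorm(-abs(point["nri"] / se)) else NA_real_
  }
  structure(list(nri = unname(point["nri"]),
                 nri_event = unname(point["nri_event"]),
                 nri_nonevent = unname(point["nri_nonevent"]),
                 ci = ci, p = unname(pval), t = t, table = tab),
            class = "nri_record")
}

nri_point <- function(risk_old, risk_new, surv, t) {
  old_high <- risk_old > stats::median(risk_old)
  new_high <- risk_new > stats::median(risk_new)
  up <- !old_high & new_high
  down <- old_high & !new_high
  km_event_prob <- function(sel) {
    if (!any(sel)) return(0)
    fit <- survival::survfit(
      survival::Surv(surv$time[sel], surv$event[sel]) ~ 1)
    1 - km_surv_at(fit, t)
  }
  p_event <- km_event_prob(rep(TRUE, nrow(surv)))
  if (p_event <= 0 || p_event >= 1)
    stop("event probability at t is degenerate (", signif(p_event, 3), ")")
  p_up <- mean(up); p_down <- mean(down)
  pe_up <- km_event_prob(up); pe_down <- km_event_prob(down)
  nri_event <- (p_up * pe_up - p_down * pe_down) / p_event
  nri_nonevent <- (p_down * (1 - pe_down) - p_up * (1 - pe_up)) / (1 - p_event)
  c(nri = nri_event + nri_nonevent,
    nri_event = nri_event, nri_nonevent = nri_nonevent)
}

#' Kaplan-Meier stratification by a risk-score split
#'
#' Splits subjects into low/high strata at the split point (median risk by
#' default), then reports the per-stratum KM curves, the log-rank p-value,
#' the high-vs-low hazard ratio from a univariate Cox fit on the group
#' indicator, and restricted-mean survival per stratum.
#'
#' @param risk numeric risk scores.
#' @param surv a `survival_table`.
#' @param split risk split point; default the median.
#' @param rmean horizon for the restricted mean (default: largest observed
#'   time).
#' @return A `km_record`: `groups`, `fit` (a `survfit`), `logrank_p`, `hr`,
#'   `hr_ci`, `hr_p`, `rmean_survival`.
#' @export
km_stratify <- function(risk, surv, split = NULL, rmean = NULL) {
  stopifnot(length(risk) == nrow(surv))
  if (is.null(split)) split <- stats::median(risk)
  group <- factor(ifelse(risk > split, "high", "low"), c("low", "high"))
  if (any(table(group) == 0)) stop("a risk stratum is empty at this split")
  y <- survival::Surv(surv$time, surv$event)
  df <- data.frame(group = group)
  fit <- survival::survfit(y ~ group, data = df)
  sd_ <- survival::survdiff(y ~ group, data = df)
  logrank_p <- stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
  if (any(tapply(surv$event, group, sum) == 0))
    warning("a stratum has zero events; the hazard ratio is a bound, not an estimate")
  cx <- survival::coxph(y ~ group, data = df)
  hr <- unname(exp(stats::coef(cx)))
  ci <- suppressMessages(exp(stats::confint(cx)))
  if (is.null(rmean)) rmean <- max(surv$time)
  tb <- summary(fit, rmean = rmean)$table
  rm_col <- grep("rmean", colnames(tb))[1]
  structure(list(groups = group, fit = fit, logrank_p = logrank_p,
                 hr = hr, hr_ci = as.numeric(ci),
                 hr_p = summary(cx)$coefficients[1, "Pr(>|z|)"],
                 rmean_survival = stats::setNames(tb[, rm_col],
                                                  rownames(tb))),
            class = "km_record")
}

#' Likelihood-ratio test between two Cox models
#'
#' Both feature sets are refit as unpenalised Cox models on the same
#' subjects. When A's features are nested in B's, returns the chi-squared
#' p-value for `2 (logPL_B - logPL_A)` on `p_B - p_A` degrees of freedom.
#' Non-nested comparisons refuse the chi-squared calibration and return the
#' log partial-likelihood difference only, with a warning.
#'
#' @param features_a,features_b data.frames of the two models' features
#'   (`NULL` = null model).
#' @param surv a `survival_table`.
#' @return list: `stat` (2 delta logPL), `df`, `p` (NA when non-nested),
#'   `loglik_a`, `loglik_b`, `nested`.
#' @export
likelihood_ratio_test <- function(features_a, features_b, surv) {
  cols <- function(f) if (is.null(f)) character(0)
                      else setdiff(colnames(as.data.frame(f)), "id")
  ca <- cols(features_a); cb <- cols(features_b)
  fa <- refit_coxph(features_a, surv)
  fb <- refit_coxph(features_b, surv)
  lla <- if (length(ca) == 0) fa$loglik[1] else fa$loglik[2]
  llb <- if (length(cb) == 0) fb$loglik[1] else fb$loglik[2]
  stat <- 2 * (llb - lla)
  nested <- all(ca %in% cb)
  df <- length(cb) - length(ca)
  if (nested && df >= 0) {
    p <- if (df == 0) 1.0 else stats::pchisq(stat, df, lower.tail = FALSE)
  } else {
    warning("models are not nested; returning the log-likelihood difference ",
            "without a chi-squared p-value")
    p <- NA_real_
  }
  list(stat = stat, df = df, p = p, loglik_a = lla, loglik_b = llb,
       nested = nested)
}

#' Per-feature hazard ratios from an unpenalised Cox refit
#'
#' @param features data.frame of features.
#' @param surv a `survival_table`.
#' @return data.frame: `feature`, `hr`, `lo`, `hi` (95% CI), `p`.
#' @export
cox_hazard_ratios <- function(features, surv) {
  fit <- refit_coxph(features, surv)
  sm <- summary(fit)$coefficients
  ci <- suppressMessages(stats::confint(fit))
  data.frame(feature = rownames(sm),
             hr = exp(sm[, "coef"]),
             lo = exp(ci[, 1]), hi = exp(ci[, 2]),
             p = sm[, "Pr(>|z|)"],
             row.names = NULL, stringsAsFactors = FALSE)
}
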