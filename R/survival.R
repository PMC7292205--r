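#' Kaplan-Meier survival curves
#'
#' Product-limit estimate of overall survival, optionally stratified by a
#' grouping column (e.g. the subtype call). Censored observations reduce
#' the at-risk count without contributing events.
#'
#' @param data Data frame with one row per subject.
#' @param time Column name (string) of the follow-up time (months, >= 0).
#' @param event Column name of the event indicator (logical or 0/1; TRUE =
#'   death observed).
#' @param group Optional column name of a grouping variable.
#' @return A tibble of class `coo_km` with columns `group`, `time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv` (plus confidence bounds
#'   `conf_low`, `conf_high`).
#' @export
km_curve <- function(data, time = "survival_time", event = "event",
                     group = NULL) {
  assert_cols(data, c(time, event, group), "survival data")
  if (nrow(data) == 0) {
    stop_coodx("no subjects in survival data", class = "coodx_validation_error")
  }
  tt <- data[[time]]
  ev <- as.logical(data[[event]])
  if (any(tt < 0) || anyNA(tt) || anyNA(ev)) {
    stop_coodx("times must be >= 0 and times/events non-missing",
               class = "coodx_validation_error")
  }
  if (is.null(group)) {
    fit <- survival::survfit(survival::Surv(tt, ev) ~ 1)
    grp <- rep("all", length(fit$time))
  } else {
    g <- factor(data[[group]])
    fit <- survival::survfit(survival::Surv(tt, ev) ~ g)
    grp <- rep(sub("^g=", "", names(fit$strata)), fit$strata)
  }
  out <- tibble(
    group = grp,
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    n_censor = fit$n.censor,
    surv = fit$surv,
    conf_low = fit$lower,
    conf_high = fit$upper
  )
  class(out) <- c("coo_km", class(out))
  out
}

#' Log-rank test across survival groups
#'
#' Unstratified k-group log-rank test: at every pooled event time the
#' observed events per group are compared with their hypergeometric
#' expectation under a common hazard; the statistic is asymptotically
#' chi-squared with k - 1 degrees of freedom.
#'
#' @inheritParams km_curve
#' @param group Column name of the grouping variable (required, >= 2
#'   non-empty groups).
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `n`.
#' @export
logrank_test <- function(data, time = "survival_time", event = "event",
                         group = "call") {
  assert_cols(data, c(time, event, group), "survival data")
  g <- factor(data[[group]])
  g <- droplevels(g)
  if (nlevels(g) < 2) {
    stop_coodx("log-rank test requires >= 2 non-empty groups",
               class = "coodx_validation_error")
  }
  tt <- data[[time]]
  ev <- as.logical(data[[event]])
  sd_fit <- survival::survdiff(survival::Surv(tt, ev) ~ g)
  df <- nlevels(g) - 1L
  tibble(
    statistic = sd_fit$chisq,
    df = df,
    p_value = stats::pchisq(sd_fit$chisq, df, lower.tail = FALSE),
    n = length(tt)
  )
}
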