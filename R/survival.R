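# Kaplan-Meier, log-rank and Cox stratification of overall survival, backed
# by the survival package.

#' Kaplan-Meier product-limit estimate
#'
#' @param times survival times (months), >= 0.
#' @param events event flags (1 = death observed, 0 = censored).
#' @return A `pex_km` object: tibble of event times (`time`, `n_at_risk`,
#'   `n_events`, `survival`, `greenwood_se`) restricted to times with at
#'   least one event, plus the underlying `survfit` in an attribute for
#'   step-function evaluation.
#' @export
km_estimator <- function(times, events) {
  if (length(times) == 0) abort("empty input")
  if (any(times < 0)) abort("times must be >= 0")
  if (!all(events %in% c(0, 1))) abort("events must be 0/1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "log")
  keep <- fit$n.event > 0
  out <- tibble(
    time = fit$time[keep],
    n_at_risk = fit$n.risk[keep],
    n_events = fit$n.event[keep],
    survival = fit$surv[keep],
    greenwood_se = (fit$surv * fit$std.err)[keep] # std.err is on the log scale
  )
  attr(out, "survfit") <- fit
  class(out) <- c("pex_km", class(out))
  out
}

#' Evaluate a Kaplan-Meier curve at a time point
#'
#' Right-continuous step-function value: 1 before the first event, the
#' last-reached survival beyond the final event.
#'
#' @param curve a `pex_km` object.
#' @param t_months time in months, >= 0.
#' @return Survival probability at `t_months`.
#' @export
survival_at <- function(curve, t_months) {
  stopifnot(inherits(curve, "pex_km"), t_months >= 0)
  if (nrow(curve) == 0 || t_months < curve$time[1]) return(1)
  curve$survival[max(which(curve$time <= t_months))]
}

#' Two-sample log-rank test
#'
#' Mantel-Haenszel observed-minus-expected statistic with hypergeometric
#' variance, 1 df.
#'
#' @param times,events as in [km_estimator()].
#' @param groups binary group indicator.
#' @return One-row tibble: `chi2`, `df`, `p`.
#' @export
logrank_test <- function(times, events, groups) {
  if (length(unique(groups)) < 2) abort("log-rank test needs two groups")
  sd_ <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- length(sd_$n) - 1
  tibble(chi2 = sd_$chisq, df = df,
         p = stats::pchisq(sd_$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards model for one binary covariate
#'
#' Partial-likelihood fit with Efron tie handling by default (Breslow
#' selectable for cross-checks); Wald 95% CI `exp(log_hr +/- 1.96 se)`.
#'
#' @param times,events as in [km_estimator()].
#' @param group binary covariate (1 = the stratum whose hazard is in the
#'   numerator).
#' @param ties `"efron"` or `"breslow"`.
#' @return A `pex_cox` object wrapping the fit; see [tidy()] / [glance()].
#' @export
cox_binary <- function(times, events, group, ties = c("efron", "breslow")) {
  ties <- arg_match(ties)
  if (length(unique(group)) < 2) abort("cox_binary needs both groups present")
  if (sum(events) < 1) abort("cox_binary needs at least one event")
  group <- as.numeric(group)
  fit <- survival::coxph(survival::Surv(times, events) ~ group,
                         ties = ties)
  log_hr <- unname(fit$coefficients)
  se <- sqrt(unname(fit$var[1, 1]))
  converged <- is.finite(log_hr) && is.finite(se) && abs(log_hr) < 15
  structure(
    list(
      log_hr = log_hr, se = se, hr = exp(log_hr),
      ci95 = c(low = exp(log_hr - 1.96 * se), high = exp(log_hr + 1.96 * se)),
      wald_p = 2 * pnorm(-abs(log_hr / se)),
      score_chi2 = unname(fit$score),
      ties_method = ties,
      converged = converged,
      n = fit$n, n_events = fit$nevent,
      fit = fit
    ),
    class = "pex_cox"
  )
}

#' @export
print.pex_cox <- function(x, ...) {
  cat(sprintf("<pex_cox> HR %.3f (95%% CI %.3f-%.3f), Wald p %.3g [%s ties]%s\n",
              x$hr, x$ci95[["low"]], x$ci95[["high"]], x$wald_p,
              x$ties_method,
              if (x$converged) "" else " [non-convergence flagged]"))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pex_cox <- function(x, ...) {
  tibble(
    term = "group", estimate = x$log_hr, std.error = x$se,
    hr = x$hr, conf.low = x$ci95[["low"]], conf.high = x$ci95[["high"]],
    p.value = x$wald_p
  )
}

#' @exportS3Method generics::glance
glance.pex_cox <- function(x, ...) {
  tibble(n = x$n, n_events = x$n_events, score_chi2 = x$score_chi2,
         ties_method = x$ties_method, converged = x$converged)
}

#' Stratified Kaplan-Meier table for plotting
#'
#' @param times,events as in [km_estimator()].
#' @param strata stratum label per subject.
#' @return Tibble of per-stratum step functions (including time 0).
#' @export
km_strata <- function(times, events, strata) {
  purrr::map_dfr(unique(strata), function(sname) {
    i <- strata == sname
    cv <- km_estimator(times[i], events[i])
    dplyr::bind_rows(
      tibble(time = 0, n_at_risk = sum(i), n_events = 0L, survival = 1,
             greenwood_se = 0),
      as_tibble(cv)
    ) %>% mutate(stratum = sname)
  })
}

#' Plot stratified Kaplan-Meier curves
#'
#' @param km_table output of [km_strata()].
#' @param ... unused.
#' @return A ggplot.
#' @export
plot_km <- function(km_table, ...) {
  ggplot2::ggplot(km_table,
                  ggplot2::aes(x = .data$time, y = .data$survival,
                               colour = .data$stratum)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Months", y = "Overall survival", colour = NULL) +
    ggplot2::theme_minimal()
}
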