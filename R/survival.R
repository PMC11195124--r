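#' Cox proportional-hazards association
#'
#' Partial-likelihood fit (Efron tie handling) of one or more covariates
#' against a time-to-event outcome, reporting the hazard ratio with Wald
#' 95% CI and p-value per covariate.
#'
#' @param surv Data frame with columns `time` (> 0) and `event` (0/1).
#' @param covariates Data frame (or named vector for a single covariate)
#'   of finite, non-constant covariates, rows aligned with `surv`.
#' @return Data frame: `covariate`, `beta`, `hr`, `ci_lower`, `ci_upper`,
#'   `pval`.
#' @export
cox_ph <- function(surv, covariates) {
  if (is.null(dim(covariates)))
    covariates <- data.frame(score = covariates)
  if (sum(surv$event) == 0) stop("no events")
  if (any(surv$time <= 0)) stop("times must be > 0")
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if (any(!is.finite(v))) stop("covariate '", nm, "' has non-finite values")
    if (stats::var(v) == 0) stop("covariate '", nm, "' is constant")
  }
  df <- cbind(surv[, c("time", "event")], covariates)
  form <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                  paste(names(covariates), collapse = " + ")))
  fit <- survival::coxph(form, data = df, ties = "efron")
  s <- summary(fit)
  data.frame(covariate = rownames(s$coefficients),
             beta = s$coefficients[, "coef"],
             hr = s$coefficients[, "exp(coef)"],
             ci_lower = s$conf.int[, "lower .95"],
             ci_upper = s$conf.int[, "upper .95"],
             pval = s$coefficients[, "Pr(>|z|)"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Kaplan-Meier curves and log-rank test
#'
#' Kaplan-Meier estimates per group with administrative censoring at a
#' stated horizon, plus the standard log-rank chi-square p-value.
#'
#' @param surv Data frame with `time`, `event`.
#' @param group Per-sample group labels (>= 2 groups).
#' @param horizon Administrative censoring horizon in the time unit of
#'   `surv` (e.g. 84 months for 7-year follow-up); `Inf` disables it.
#' @return List: `curves` (data frame `group`, `time`, `surv`, `n_risk`),
#'   `logrank_chisq`, `pval`.
#' @export
km_logrank <- function(surv, group, horizon = Inf) {
  group <- as.factor(group)
  if (nlevels(group) < 2) stop("need >= 2 groups")
  time <- pmin(surv$time, horizon)
  event <- ifelse(surv$time > horizon, 0L, surv$event)
  if (sum(event) == 0) stop("no events within the horizon")
  df <- data.frame(time = time, event = event, group = group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  strata <- rep(names(fit$strata), fit$strata)
  curves <- data.frame(group = sub("^group=", "", strata),
                       time = fit$time, surv = fit$surv,
                       n_risk = fit$n.risk, stringsAsFactors = FALSE)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  list(curves = curves, logrank_chisq = sd_$chisq,
       pval = stats::pchisq(sd_$chisq, df = nlevels(group) - 1,
                            lower.tail = FALSE))
}
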