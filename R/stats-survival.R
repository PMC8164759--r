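#' Kaplan-Meier curves with log-rank test
#'
#' Product-limit survival estimates per group plus the two-group log-rank
#' test (chi-square, 1 df).
#'
#' @param time Follow-up times (>= 0).
#' @param event Event indicators in `{0, 1}`.
#' @param group Two-level grouping vector.
#' @return List with `fit` (a [survival::survfit] object), `test` (a
#'   [test_result()]), and `n` per group. Errors if a group is empty or no
#'   events occurred anywhere (the test is undefined on event-free data).
#' @export
km_logrank <- function(time, event, group) {
  ok <- !is.na(time) & !is.na(event) & !is.na(group)
  time <- time[ok]; event <- event[ok]; group <- droplevels(factor(group[ok]))
  if (any(time < 0)) stop("times must be non-negative")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  if (nlevels(group) != 2L) stop("exactly two non-empty groups are required")
  if (any(table(group) == 0L)) stop("a group has zero subjects")
  if (sum(event) == 0L) {
    stop("log-rank test undefined: no events observed in either group")
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(
    fit = fit,
    test = test_result(
      "logrank", statistic = sd$chisq, df = 1L,
      p_value = stats::pchisq(sd$chisq, 1, lower.tail = FALSE),
      n = as.integer(table(group))
    ),
    n = table(group)
  )
}

#' Cox proportional-hazards regression
#'
#' Partial-likelihood fit (Efron tie handling) returning hazard ratios with
#' Wald confidence intervals and p-values per covariate. Non-convergence or
#' effectively infinite coefficients (complete separation) raise an explicit
#' error rather than returning a spurious fit.
#'
#' @param time Follow-up times (>= 0).
#' @param event Event indicators in `{0, 1}` (at least one event).
#' @param covariates Data frame of numeric or factor covariates.
#' @param conf_level Confidence level for the hazard-ratio intervals.
#' @return List with `model` (the [survival::coxph] fit), `hazard_ratios`
#'   (data frame: term, hr, lower, upper, p), and `tests` (list of Wald
#'   [test_result()] per term).
#' @export
cox_regression <- function(time, event, covariates, conf_level = 0.95) {
  if (!is.data.frame(covariates)) covariates <- as.data.frame(covariates)
  dat <- cbind(data.frame(.time = time, .event = event), covariates)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (nrow(dat) == 0L) stop("no complete cases")
  if (any(dat$.time < 0)) stop("times must be non-negative")
  if (!all(dat$.event %in% c(0, 1))) stop("event must be 0/1")
  if (sum(dat$.event) < 1L) stop("Cox regression requires at least one event")
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(covariates)), collapse = " + ")
  ))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|did not converge|Loglik converged", conditionMessage(w))) {
        stop("Cox fit failed: non-convergence or complete separation (",
             conditionMessage(w), ")", call. = FALSE)
      }
      invokeRestart("muffleWarning")
    }
  )
  if (any(!is.finite(stats::coef(fit))) || any(abs(stats::coef(fit)) > 20)) {
    stop("Cox fit failed: coefficient diverged (complete separation?)")
  }
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  wald_z <- beta / se
  p <- 2 * stats::pnorm(-abs(wald_z))
  hr <- data.frame(
    term = names(beta),
    hr = exp(beta),
    lower = exp(beta - zq * se),
    upper = exp(beta + zq * se),
    p = p,
    row.names = NULL
  )
  tests <- lapply(seq_along(beta), function(i) {
    test_result(
      sprintf("cox_wald[%s]", names(beta)[i]),
      statistic = wald_z[i], p_value = p[i], n = nrow(dat),
      extra = list(hr = unname(exp(beta[i])), events = sum(dat$.event))
    )
  })
  list(model = fit, hazard_ratios = hr, tests = tests)
}
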