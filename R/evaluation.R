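#' Harrell's concordance index
#'
#' Fraction of comparable patient pairs whose predicted risk ordering
#' matches the survival ordering. A pair `(m, n)` is comparable when
#' `t_m < t_n` and the shorter time is an observed event; tied times are
#' excluded. The pair scores 1 when the shorter-lived patient has the
#' strictly higher risk, 0.5 on tied risks, 0 otherwise. 1 is perfect
#' concordance, 0 perfect anti-concordance, 0.5 random.
#'
#' @param risks numeric risk scores (higher = predicted higher hazard).
#' @param times survival / follow-up times.
#' @param events 0/1 event indicators.
#' @return c-index in `[0, 1]`.
#' @export
concordance_index <- function(risks, times, events) {
  n <- length(risks)
  stopifnot(length(times) == n, length(events) == n)
  if (n < 2L) stop_validation("c-index undefined: need at least 2 subjects")
  lt <- outer(times, times, "<")            # [m, n] : t_m < t_n
  comp <- lt & (events == 1)                # event vector recycles over rows m
  nq <- sum(comp)
  if (nq == 0L) stop_validation("c-index undefined: no comparable pairs")
  gt <- outer(risks, risks, ">")
  eq <- outer(risks, risks, "==")
  (sum(gt[comp]) + 0.5 * sum(eq[comp])) / nq
}

#' Median-threshold risk stratification
#'
#' Labels each patient `high` when the risk exceeds the cohort median and
#' `low` otherwise (risks equal to the median go to `low`, giving a
#' deterministic split). The median should be computed over the pooled
#' cross-validated cohort risks.
#'
#' @param risks numeric patient-level risks (>= 2).
#' @return factor with levels `low`, `high`.
#' @export
stratify_median <- function(risks) {
  if (length(risks) < 2L) stop_validation("stratify_median needs >= 2 patients")
  med <- stats::median(risks)
  if (all(risks == risks[1L])) {
    warning("all risks equal; every patient assigned to the 'low' stratum")
  }
  factor(ifelse(risks > med, "high", "low"), levels = c("low", "high"))
}

#' Kaplan-Meier product-limit estimate
#'
#' `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over the observed time points.
#'
#' @param times survival times.
#' @param events 0/1 indicators.
#' @return object of class `km_estimate`: `event_times` (sorted distinct
#'   observed times), `survival` (step values of S), `at_risk`, `events`.
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0L) stop_validation("km_estimate: empty input")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  structure(list(event_times = fit$time, survival = fit$surv,
                 at_risk = fit$n.risk, events = fit$n.event),
            class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  cat(sprintf("<km_estimate> %d time points, final S = %.3f\n",
              length(x$event_times), utils::tail(x$survival, 1L)))
  invisible(x)
}

#' Evaluate a Kaplan-Meier estimate at arbitrary times
#'
#' @param km a `km_estimate`.
#' @param t times at which to evaluate the step function.
#' @return numeric vector `S(t)`.
#' @export
km_survival_at <- function(km, t) {
  vapply(t, function(ti) {
    idx <- which(km$event_times <= ti)
    if (length(idx) == 0L) 1 else km$survival[max(idx)]
  }, 0)
}

#' Two-group log-rank test
#'
#' Standard two-group log-rank chi-square statistic (1 degree of freedom)
#' with a two-sided p-value from the chi-square upper tail, plus the
#' observed/expected (Mantel-Haenszel) hazard-ratio estimate
#' `(O_2 / E_2) / (O_1 / E_1)` of the second group versus the first.
#'
#' @param times survival times.
#' @param events 0/1 indicators.
#' @param groups vector with exactly two distinct values, both nonempty.
#' @return list `chi2`, `p_value`, `hazard_ratio`.
#' @export
logrank_test <- function(times, events, groups) {
  g <- factor(groups)
  if (nlevels(g) != 2L) stop_validation("logrank_test needs exactly 2 nonempty groups")
  fit <- survival::survdiff(survival::Surv(times, events) ~ g)
  hr <- (fit$obs[2L] / fit$exp[2L]) / (fit$obs[1L] / fit$exp[1L])
  list(chi2 = unname(fit$chisq),
       p_value = stats::pchisq(fit$chisq, df = 1L, lower.tail = FALSE),
       hazard_ratio = unname(hr))
}

#' Proportional-hazards regression with hazard ratios
#'
#' Fits the Cox model by Newton-Raphson maximisation of the partial
#' likelihood with Breslow tie handling, reporting per covariate the hazard
#' ratio `exp(coef)` with its Wald 95 percent interval `exp(coef +/- 1.96 se)`,
#' the Wald p-value, and Harrell's c-index of the fit's linear predictor.
#' In univariable mode each covariate is fit alone; in multivariable mode
#' all covariates enter one model. Monotone likelihoods (perfect
#' separation) are flagged as non-converged with no estimates.
#'
#' @param covariates data.frame of numeric or factor covariates.
#' @param times survival times.
#' @param events 0/1 indicators.
#' @param mode `"univariable"` or `"multivariable"`.
#' @return data.frame of class `cox_fit` with columns `variable`, `coef`,
#'   `hazard_ratio`, `ci_low`, `ci_high`, `p_value`, `c_index`, `converged`.
#' @export
cox_regression <- function(covariates, times, events,
                           mode = c("univariable", "multivariable")) {
  mode <- match.arg(mode)
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(covariates) == length(times), length(times) == length(events))
  constant <- vapply(covariates, function(v) length(unique(v)) < 2L, TRUE)
  if (any(constant)) {
    stop_validation("constant covariate(s): %s", paste(names(covariates)[constant], collapse = ", "))
  }
  if (sum(events) < ncol(covariates) + 1L) {
    stop_validation("too few events (%d) for %d covariate(s)", sum(events), ncol(covariates))
  }
  fit_one <- function(df) {
    df$.time <- times
    df$.event <- events
    warned <- FALSE
    fit <- withCallingHandlers(
      survival::coxph(survival::Surv(.time, .event) ~ ., data = df, ties = "breslow"),
      warning = function(w) {
        warned <<- TRUE
        invokeRestart("muffleWarning")
      })
    s <- summary(fit)
    co <- s$coefficients
    converged <- !warned && all(is.finite(co[, "se(coef)"])) && all(co[, "se(coef)"] < 1e3)
    lp <- fit$linear.predictors
    ci <- tryCatch(concordance_index(lp, times, events), error = function(e) NA_real_)
    data.frame(
      variable = rownames(co),
      coef = if (converged) co[, "coef"] else NA_real_,
      hazard_ratio = if (converged) exp(co[, "coef"]) else NA_real_,
      ci_low = if (converged) exp(co[, "coef"] - 1.96 * co[, "se(coef)"]) else NA_real_,
      ci_high = if (converged) exp(co[, "coef"] + 1.96 * co[, "se(coef)"]) else NA_real_,
      p_value = if (converged) co[, "Pr(>|z|)"] else NA_real_,
      c_index = ci,
      converged = converged,
      row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- if (mode == "univariable") {
    do.call(rbind, lapply(names(covariates), function(v) fit_one(covariates[, v, drop = FALSE])))
  } else {
    fit_one(covariates)
  }
  class(out) <- c("cox_fit", "data.frame")
  out
}
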