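# Survival analysis: Kaplan-Meier estimates, Cox proportional-hazards models
# (unadjusted and covariate-adjusted) and treatment-by-biomarker interaction
# tests. Thin, validated wrappers around the survival package with tidy
# outputs; tied event times use the Efron approximation throughout.

#' Kaplan-Meier fit
#'
#' Product-limit survival estimate, optionally by group, with median
#' survival and 95% CI per group; an unreached median is reported as `NA`
#' ("not reached").
#'
#' @param data data frame.
#' @param time,event column names (event must be 0/1).
#' @param group optional grouping column name.
#' @return object of class `km_fit`; [tidy()] gives the step function
#'   (time, n.risk, n.event, estimate, conf intervals, group), [glance()]
#'   the per-group n, events and median with CI.
#' @export
km_fit <- function(data, time = "os_months", event = "os_event", group = NULL) {
  assert_cols(data, c(time, event, group), "data")
  if (any(data[[time]] < 0, na.rm = TRUE)) abort("negative survival times")
  if (!all(data[[event]] %in% c(0, 1))) abort("event must be 0/1")
  df <- data.frame(.time = data[[time]], .event = data[[event]])
  if (!is.null(group)) {
    df$.group <- as.factor(data[[group]])
    fit <- survival::survfit(survival::Surv(.time, .event) ~ .group, data = df)
  } else {
    fit <- survival::survfit(survival::Surv(.time, .event) ~ 1, data = df)
  }
  structure(list(fit = fit, group = group), class = "km_fit")
}

#' @rdname km_fit
#' @param x,... a `km_fit`.
#' @export
tidy.km_fit <- function(x, ...) {
  f <- x$fit
  strata <- if (is.null(f$strata)) {
    rep("all", length(f$time))
  } else {
    rep(sub("^\\.group=", "", names(f$strata)), f$strata)
  }
  tibble(group = strata, time = f$time, n_risk = f$n.risk,
         n_event = f$n.event, n_censor = f$n.censor, estimate = f$surv,
         conf.low = f$lower, conf.high = f$upper)
}

#' @rdname km_fit
#' @export
glance.km_fit <- function(x, ...) {
  tab <- summary(x$fit)$table
  if (is.null(dim(tab))) tab <- matrix(tab, 1, dimnames = list("all", names(tab)))
  tibble(group = sub("^\\.group=", "", rownames(tab)),
         n = tab[, "records"], events = tab[, "events"],
         median = tab[, "median"],
         conf.low = tab[, "0.95LCL"], conf.high = tab[, "0.95UCL"])
}

#' @export
print.km_fit <- function(x, ...) {
  cat("<km_fit>\n")
  print(glance(x))
  invisible(x)
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood estimation with the Efron approximation for ties.
#' `terms` are the covariates of interest; `adjust` appends baseline
#' adjustment covariates. Non-convergence or a monotone likelihood
#' (infinite coefficient) raises an error with diagnostics rather than
#' returning a silently unstable fit.
#'
#' @param data data frame containing all columns.
#' @param time,event survival column names.
#' @param terms character vector of covariate column names.
#' @param adjust optional character vector of adjustment covariates.
#' @return object of class `cox_fit`; [tidy()] gives per-coefficient log-HR,
#'   HR, 95% CI, Wald z and two-sided p; [glance()] n, events, concordance
#'   and likelihood.
#' @export
cox_fit <- function(data, time = "os_months", event = "os_event",
                    terms, adjust = NULL) {
  covs <- c(terms, adjust)
  assert_cols(data, c(time, event, covs), "data")
  if (sum(data[[event]]) < 2) abort("need at least 2 events")
  const <- covs[vapply(covs, function(v) length(unique(data[[v]])) < 2, logical(1))]
  if (length(const) > 0) {
    abort(sprintf("constant covariate(s): %s", paste(const, collapse = ", ")))
  }
  fml <- stats::as.formula(paste0(
    "survival::Surv(", time, ", ", event, ") ~ ",
    paste(covs, collapse = " + ")
  ))
  fit <- survival::coxph(fml, data = data, ties = "efron")
  check_cox_convergence(fit)
  structure(list(fit = fit, terms = terms, adjust = adjust,
                 adjusted = !is.null(adjust)), class = "cox_fit")
}

check_cox_convergence <- function(fit) {
  beta <- coef(fit)
  se <- sqrt(diag(fit$var))
  if (any(!is.finite(beta)) || any(!is.finite(se)) || any(abs(beta) > 15)) {
    abort(sprintf(
      "Cox fit did not converge (monotone likelihood?): coef = %s",
      paste(sprintf("%.3g", beta), collapse = ", ")))
  }
  invisible(fit)
}

#' @rdname cox_fit
#' @param x,... a `cox_fit`.
#' @export
tidy.cox_fit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  ci <- summary(x$fit)$conf.int
  tibble(term = rownames(sm),
         estimate = unname(sm[, "coef"]),
         hr = unname(sm[, "exp(coef)"]),
         conf.low = unname(ci[, "lower .95"]),
         conf.high = unname(ci[, "upper .95"]),
         statistic = unname(sm[, "z"]),
         p_value = unname(sm[, "Pr(>|z|)"]),
         adjusted = x$adjusted)
}

#' @rdname cox_fit
#' @export
glance.cox_fit <- function(x, ...) {
  f <- x$fit
  tibble(n = f$n, events = f$nevent,
         concordance = unname(f$concordance["concordance"]),
         loglik = f$loglik[2], adjusted = x$adjusted)
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit>%s\n", if (x$adjusted) " (covariate-adjusted)" else ""))
  print(tidy(x))
  invisible(x)
}

#' Treatment-by-biomarker interaction test
#'
#' Fits `Surv ~ treatment + biomarker + treatment:biomarker` (plus optional
#' adjustment covariates) and reports the Wald test of the product term.
#' Continuous biomarkers are used untransformed; median-split group labels
#' can be passed as a binary biomarker for display-oriented analyses.
#'
#' @param data data frame.
#' @param time,event survival column names.
#' @param treatment binary treatment column (0/1, logical or two-level
#'   factor).
#' @param biomarker biomarker column (continuous or binary).
#' @param adjust optional adjustment covariate names.
#' @return one-row tibble: interaction log-HR (`estimate`), `hr`, 95% CI,
#'   Wald `statistic`, `p_value`, `n`, `events`, `adjusted`.
#' @export
interaction_test <- function(data, time = "os_months", event = "os_event",
                             treatment, biomarker, adjust = NULL) {
  assert_cols(data, c(time, event, treatment, biomarker, adjust), "data")
  df <- data
  df$.treat <- binarize(df[[treatment]], treatment)
  df$.bio <- if (is.numeric(df[[biomarker]])) df[[biomarker]] else {
    binarize(df[[biomarker]], biomarker)
  }
  fml <- stats::as.formula(paste0(
    "survival::Surv(", time, ", ", event, ") ~ .treat * .bio",
    if (length(adjust) > 0) paste0(" + ", paste(adjust, collapse = " + ")) else ""
  ))
  fit <- survival::coxph(fml, data = df, ties = "efron")
  check_cox_convergence(fit)
  sm <- summary(fit)$coefficients
  row <- ".treat:.bio"
  if (!row %in% rownames(sm)) abort("interaction term inestimable")
  est <- sm[row, "coef"]; se <- sm[row, "se(coef)"]
  tibble(term = paste0(treatment, ":", biomarker),
         estimate = est, hr = exp(est),
         conf.low = exp(est - qnorm(0.975) * se),
         conf.high = exp(est + qnorm(0.975) * se),
         statistic = sm[row, "z"], p_value = sm[row, "Pr(>|z|)"],
         n = fit$n, events = fit$nevent, adjusted = length(adjust) > 0)
}

binarize <- function(x, what) {
  u <- sort(unique(as.character(x)))
  if (is.numeric(x) && all(x %in% c(0, 1))) return(as.numeric(x))
  if (is.logical(x)) return(as.numeric(x))
  if (length(u) != 2) abort(sprintf("%s must be binary (got %d levels)", what, length(u)))
  as.numeric(as.character(x) == u[2])
}
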