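# Mutation-acquisition rates: per-patient rates with time-on-treatment as
# exposure, a Poisson mixture (EM with offsets) identifying low/medium/high
# rate subgroups, and a negative-binomial arm comparison.

#' Per-patient acquisition rates
#'
#' Counts acquired-status alterations per patient and divides by time on
#' treatment (a constant acquisition rate over the treatment interval is
#' assumed). Every patient in `patients` gets a row — patients with no
#' acquired alterations have count 0. `display_rate` recodes exact zeros to
#' half the smallest nonzero rate so they can sit on a log axis.
#'
#' @param status_records output of [classify_alteration_status()] across
#'   patients (or of [aggregate_gene_status()]; any table with `patient_id`
#'   and a status column works).
#' @param patients patient table with `patient_id`, `arm`,
#'   `time_on_treatment_months` (> 0).
#' @param status_col name of the status column (default `"status"`).
#' @return tibble: `patient_id`, `arm`, `acquired_count`, `exposure_months`,
#'   `rate_per_month`, `display_rate`.
#' @export
compute_rates <- function(status_records, patients, status_col = "status") {
  assert_cols(patients, c("patient_id", "arm", "time_on_treatment_months"),
              "patient table")
  if (anyNA(patients$time_on_treatment_months) ||
      any(patients$time_on_treatment_months <= 0)) {
    abort("every patient needs time_on_treatment_months > 0")
  }
  assert_cols(status_records, c("patient_id", status_col), "status records")
  counts <- status_records %>%
    filter(.data[[status_col]] == "acquired") %>%
    dplyr::count(.data$patient_id, name = "acquired_count")
  out <- patients %>%
    select("patient_id", "arm", exposure_months = "time_on_treatment_months") %>%
    left_join(counts, by = "patient_id") %>%
    mutate(acquired_count = dplyr::coalesce(.data$acquired_count, 0L),
           rate_per_month = .data$acquired_count / .data$exposure_months)
  nz <- out$rate_per_month[out$rate_per_month > 0]
  floor_rate <- if (length(nz) > 0) min(nz) / 2 else NA_real_
  out %>% mutate(display_rate = if_else(.data$rate_per_month == 0,
                                        floor_rate, .data$rate_per_month))
}

poisson_mixture_loglik <- function(y, t, weights, rates) {
  comp <- vapply(seq_along(rates), function(k) {
    dpois(y, rates[k] * t, log = TRUE) + log(weights[k])
  }, numeric(length(y)))
  if (length(y) == 1) comp <- matrix(comp, nrow = 1)
  m <- apply(comp, 1, max)
  sum(m + log(rowSums(exp(comp - m))))
}

#' Fit a Poisson mixture to acquisition counts with exposure offsets
#'
#' EM for the model `count_i ~ Poisson(lambda_k * t_i)` with mixing weights
#' `w_k`, identifying rate subgroups (e.g. low/medium/high at the default
#' K = 3). The fit is the best of `n_restarts` seeded restarts initialised by
#' a quantile split of the observed rates plus jitter; components are
#' reported in ascending rate order so the fit is invariant to label
#' permutation and patient order. The log-likelihood is checked to be
#' nondecreasing at every EM iteration.
#'
#' @param observations output of [compute_rates()] (needs `acquired_count`
#'   and `exposure_months`).
#' @param K number of components (>= 1).
#' @param n_restarts EM restarts (default 20).
#' @param seed integer seed for restart jitter.
#' @param max_iter,tol EM iteration cap and convergence tolerance on the
#'   log-likelihood change.
#' @return object of class `poisson_mixture`: weights, rates,
#'   responsibilities, assignments, loglik, BIC, convergence info. Methods:
#'   [tidy()] (one row per component), [glance()] (fit summary),
#'   [augment()] (per-patient assignment).
#' @export
fit_poisson_mixture <- function(observations, K = 3, n_restarts = 20,
                                seed = 1L, max_iter = 500, tol = 1e-8) {
  assert_cols(observations, c("acquired_count", "exposure_months"), "observations")
  y <- observations$acquired_count
  t <- observations$exposure_months
  n <- length(y)
  if (K < 1) abort("K must be >= 1")
  if (n < K) abort("need at least K observations")
  if (any(t <= 0) || any(y < 0)) abort("need exposures > 0 and counts >= 0")
  if (all(y == 0) && K > 1) {
    warn("all counts are zero: mixture fit with K > 1 is degenerate")
  }

  if (K == 1) {
    lambda <- sum(y) / sum(t)
    ll <- poisson_mixture_loglik(y, t, 1, lambda)
    return(new_poisson_mixture(weights = 1, rates = lambda,
                               resp = matrix(1, n, 1), loglik = ll,
                               converged = TRUE, n_iter = 1L, y = y, t = t,
                               observations = observations))
  }

  rates_obs <- y / t
  qs <- quantile(rates_obs, probs = (seq_len(K) - 0.5) / K, names = FALSE)
  overall <- sum(y) / sum(t)
  qs[qs <= 0] <- overall * 10^(seq_len(sum(qs <= 0)) - sum(qs <= 0) - 1)
  qs[qs <= 0] <- 1e-4

  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      init <- if (r == 1) qs else qs * exp(rnorm(K, 0, 0.5))
      fit <- try(em_poisson_mixture(y, t, sort(pmax(init, 1e-8)),
                                    max_iter = max_iter, tol = tol),
                 silent = TRUE)
      if (inherits(fit, "try-error")) next
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
  })
  if (is.null(best)) abort("all EM restarts failed")
  ord <- order(best$rates)
  new_poisson_mixture(weights = best$weights[ord], rates = best$rates[ord],
                      resp = best$resp[, ord, drop = FALSE],
                      loglik = best$loglik, converged = best$converged,
                      n_iter = best$n_iter, y = y, t = t,
                      observations = observations)
}

em_poisson_mixture <- function(y, t, rates, max_iter, tol) {
  K <- length(rates)
  n <- length(y)
  weights <- rep(1 / K, K)
  ll_old <- -Inf
  converged <- FALSE
  resp <- matrix(0, n, K)
  for (iter in seq_len(max_iter)) {
    logp <- vapply(seq_len(K), function(k) {
      dpois(y, rates[k] * t, log = TRUE) + log(weights[k])
    }, numeric(n))
    if (n == 1) logp <- matrix(logp, nrow = 1)
    m <- apply(logp, 1, max)
    lse <- m + log(rowSums(exp(logp - m)))
    resp <- exp(logp - lse)
    ll <- sum(lse)
    # EM guarantees monotone log-likelihood; assert it every iteration
    if (ll < ll_old - 1e-8) {
      abort(sprintf("EM log-likelihood decreased at iteration %d", iter))
    }
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
    weights <- pmax(colMeans(resp), 1e-12)
    weights <- weights / sum(weights)
    rates <- pmax(colSums(resp * y) / colSums(resp * t), 1e-12)
  }
  list(weights = weights, rates = rates, resp = resp, loglik = ll_old,
       converged = converged, n_iter = iter)
}

new_poisson_mixture <- function(weights, rates, resp, loglik, converged,
                                n_iter, y, t, observations) {
  K <- length(rates)
  n <- length(y)
  n_par <- (K - 1) + K
  structure(list(
    K = K, weights = unname(weights), rates = unname(rates),
    responsibilities = unname(resp),
    assignments = max.col(resp, ties.method = "first"),
    loglik = loglik, bic = -2 * loglik + n_par * log(n),
    converged = converged, n_iter = n_iter,
    counts = y, exposures = t, observations = observations
  ), class = "poisson_mixture")
}

#' @export
print.poisson_mixture <- function(x, ...) {
  cat(sprintf("<poisson_mixture> K = %d, n = %d, loglik = %.3f, BIC = %.3f%s\n",
              x$K, length(x$counts), x$loglik, x$bic,
              if (x$converged) "" else " (not converged)"))
  print(tidy(x))
  invisible(x)
}

#' @rdname fit_poisson_mixture
#' @param x,... a `poisson_mixture` fit.
#' @export
tidy.poisson_mixture <- function(x, ...) {
  tibble(component = seq_len(x$K), weight = x$weights, rate_per_month = x$rates,
         n_assigned = as.integer(tabulate(x$assignments, x$K)))
}

#' @rdname fit_poisson_mixture
#' @export
glance.poisson_mixture <- function(x, ...) {
  tibble(K = x$K, loglik = x$loglik, bic = x$bic, converged = x$converged,
         n_iter = x$n_iter, n = length(x$counts))
}

#' @rdname fit_poisson_mixture
#' @export
augment.poisson_mixture <- function(x, ...) {
  x$observations %>%
    mutate(component = x$assignments,
           max_responsibility = apply(x$responsibilities, 1, max))
}

#' BIC scan over mixture sizes
#'
#' Fits [fit_poisson_mixture()] for each K and reports BIC — the default
#' K = 3 (low/medium/high) can thereby be sanity-checked against the data.
#'
#' @param observations as in [fit_poisson_mixture()].
#' @param K_range integer vector of component counts (default 1:5).
#' @inheritParams fit_poisson_mixture
#' @return tibble of [glance()] rows, one per K.
#' @export
scan_poisson_mixture <- function(observations, K_range = 1:5, n_restarts = 20,
                                 seed = 1L) {
  purrr::map_dfr(K_range, function(k) {
    glance(fit_poisson_mixture(observations, K = k, n_restarts = n_restarts,
                               seed = seed))
  })
}

#' Negative-binomial comparison of acquisition rates across arms
#'
#' Regresses acquired counts on arm indicators with `log(exposure)` offsets
#' using a negative-binomial GLM (dispersion by maximum likelihood);
#' exponentiated coefficients are acquisition-rate ratios versus the
#' reference arm, with Wald 95% CIs. If the NB fit fails (e.g. no evidence
#' of overdispersion driving theta to infinity), a Poisson GLM is used and
#' flagged in the output.
#'
#' @param observations output of [compute_rates()].
#' @param reference_arm arm used as the rate-ratio denominator.
#' @param conf_level confidence level (default 0.95).
#' @return tibble: one row per non-reference arm with `rate_ratio`,
#'   `conf.low`, `conf.high`, `p_value`, `family` ("negative_binomial" or
#'   "poisson_fallback") and `theta` (NB dispersion, `NA` for fallback).
#' @export
compare_rates_nb <- function(observations, reference_arm = "control",
                             conf_level = 0.95) {
  assert_cols(observations, c("arm", "acquired_count", "exposure_months"),
              "observations")
  arms <- unique(observations$arm)
  if (!reference_arm %in% arms) abort("reference_arm not present in data")
  if (length(arms) < 2) abort("need at least two arms")
  small <- observations %>% dplyr::count(.data$arm) %>% filter(.data$n < 2)
  if (nrow(small) > 0) abort("every arm needs at least 2 patients")
  dat <- observations %>%
    mutate(arm = stats::relevel(factor(.data$arm), ref = reference_arm),
           off = log(.data$exposure_months))

  fam <- "negative_binomial"
  theta <- NA_real_
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(acquired_count ~ arm + offset(off), data = dat)),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$converged) {
    fam <- "poisson_fallback"
    fit <- glm(acquired_count ~ arm + offset(off), data = dat, family = poisson())
    warn("negative-binomial fit failed; falling back to Poisson GLM")
  } else {
    theta <- fit$theta
  }
  sm <- summary(fit)$coefficients
  rows <- grep("^arm", rownames(sm), value = TRUE)
  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble(
    arm = sub("^arm", "", rows),
    reference = reference_arm,
    rate_ratio = exp(sm[rows, "Estimate"]),
    conf.low = exp(sm[rows, "Estimate"] - z * sm[rows, "Std. Error"]),
    conf.high = exp(sm[rows, "Estimate"] + z * sm[rows, "Std. Error"]),
    p_value = sm[rows, 4],
    family = fam,
    theta = theta
  )
}
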