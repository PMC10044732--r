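#' Fit a logistic regression by maximum likelihood
#'
#' Binomial-family GLM fit by iteratively reweighted least squares
#' (convergence tolerance 1e-8, at most 100 iterations) with Wald standard
#' errors from the inverse observed information. Perfect separation is
#' detected from diverging coefficients and raised as an explicit error;
#' other non-convergence is returned as a flagged fit.
#'
#' @param outcome Binary (0/1 or logical) response vector.
#' @param design Data frame of covariates (complete cases required).
#' @return An object of class `ses_logistic`: `coefficients` (data frame
#'   with `term`, `estimate`, `se`), `log_likelihood`, `aic`, `n`,
#'   `converged`, and the underlying `glm` object as `fit`.
#' @export
fit_logistic <- function(outcome, design) {
  outcome <- as.integer(outcome)
  stopifnot(is.data.frame(design), nrow(design) == length(outcome))
  if (anyNA(outcome) || anyNA(design)) {
    stop_ses("missing values; pass complete cases", class = "outcome_error")
  }
  if (length(unique(outcome)) < 2L) {
    stop_ses("outcome must contain both classes", class = "outcome_error")
  }
  dat <- cbind(data.frame(.y = outcome), design)
  fml <- if (ncol(design) == 0L) .y ~ 1 else .y ~ .
  fit <- suppressWarnings(
    stats::glm(fml, data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  )
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop_ses("rank-deficient design (aliased coefficients)",
             class = "outcome_error")
  }
  if (any(abs(cf[-1L]) > 15)) {
    stop_ses("perfect separation detected (diverging coefficients)",
             class = "outcome_separation_error")
  }
  ll <- as.numeric(stats::logLik(fit))
  npar <- length(cf)
  structure(list(
    coefficients = data.frame(term = names(cf), estimate = unname(cf),
                              se = sqrt(diag(stats::vcov(fit)))),
    log_likelihood = ll,
    aic = 2 * npar - 2 * ll,
    n = length(outcome),
    converged = fit$converged,
    fit = fit
  ), class = "ses_logistic")
}

#' @export
print.ses_logistic <- function(x, ...) {
  cat("<ses_logistic> n = ", x$n, ", logLik = ",
      sprintf("%.3f", x$log_likelihood), ", AIC = ",
      sprintf("%.2f", x$aic), if (!x$converged) "  [NOT CONVERGED]", "\n",
      sep = "")
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

#' Age- and gender-adjusted SES/outcome logistic model
#'
#' Regresses asthma history on an ordinal SES variable (3, 4 or 5
#' categories), adjusting for age in years and a female indicator.
#' Complete cases over outcome, SES, age and gender. Two codings are
#' fitted: dummy coding of the SES categories (odds ratios with Wald 95%
#' CIs against the lowest category) and numeric coding (a single
#' per-category-step odds ratio whose Wald p-value is the linear-trend
#' test). The linear-trend association is summarised both ways: monotone
#' non-decreasing OR point estimates across ordered categories, and the
#' numeric-coded trend p-value.
#'
#' @param cohort A [ses_cohort][as_cohort] supplying `asthma_history`,
#'   `age` and `gender`.
#' @param ses_categories Integer vector of SES categories 1..k aligned
#'   with the cohort rows (`NA` rows are dropped).
#' @param coding Which fit to report as the primary `fit`/`aic`:
#'   `"dummy"` (default, matches the published table layout) or
#'   `"numeric"`.
#' @return An object of class `ses_outcome_fit`: `fit`, `or_table`
#'   (category, or, ci_low, ci_high), `trend_or`, `trend_p`,
#'   `trend_monotone`, `aic`, `n`, `k`, plus `dummy_fit` and `trend_fit`.
#' @export
fit_ses_outcome_model <- function(cohort, ses_categories,
                                  coding = c("dummy", "numeric")) {
  coding <- match.arg(coding)
  stopifnot(inherits(cohort, "ses_cohort"),
            length(ses_categories) == nrow(cohort))
  keep <- !is.na(ses_categories) & !is.na(cohort$asthma_history) &
    !is.na(cohort$age) & !is.na(cohort$gender)
  ses <- as.integer(ses_categories[keep])
  y <- cohort$asthma_history[keep]
  age <- cohort$age[keep]
  female <- as.integer(cohort$gender[keep] == "female")
  k <- max(ses)

  dummy_design <- data.frame(age = age, female = female)
  for (cat in 2:k) dummy_design[[paste0("ses", cat)]] <- as.integer(ses == cat)
  dummy_fit <- fit_logistic(y, dummy_design)

  trend_fit <- fit_logistic(y, data.frame(ses = ses, age = age,
                                          female = female))

  cf <- dummy_fit$coefficients
  ses_rows <- cf[grepl("^ses", cf$term), , drop = FALSE]
  or_table <- data.frame(
    category = seq_len(k),
    or = c(1, exp(ses_rows$estimate)),
    ci_low = c(NA, exp(ses_rows$estimate - 1.96 * ses_rows$se)),
    ci_high = c(NA, exp(ses_rows$estimate + 1.96 * ses_rows$se))
  )
  tr <- trend_fit$coefficients[trend_fit$coefficients$term == "ses", ]
  trend_p <- 2 * stats::pnorm(-abs(tr$estimate / tr$se))

  primary <- if (coding == "dummy") dummy_fit else trend_fit
  structure(list(
    fit = primary, dummy_fit = dummy_fit, trend_fit = trend_fit,
    or_table = or_table,
    trend_or = exp(tr$estimate), trend_p = trend_p,
    trend_monotone = !is.unsorted(or_table$or),
    aic = primary$aic, n = primary$n, k = k, coding = coding
  ), class = "ses_outcome_fit")
}

#' @export
print.ses_outcome_fit <- function(x, ...) {
  cat("<ses_outcome_fit> k = ", x$k, ", n = ", x$n, ", AIC = ",
      sprintf("%.2f", x$aic), "\n", sep = "")
  tab <- x$or_table
  tab$`OR (95% CI)` <- ifelse(
    tab$category == 1, "Reference",
    sprintf("%.2f (%.2f to %.2f)", tab$or, tab$ci_low, tab$ci_high))
  print(tab[, c("category", "OR (95% CI)")], row.names = FALSE)
  cat("trend OR per step ", sprintf("%.3f", x$trend_or), " (p = ",
      sprintf("%.3g", x$trend_p), "); monotone ORs: ",
      x$trend_monotone, "\n", sep = "")
  invisible(x)
}

#' Compare two SES/outcome fits
#'
#' For two logistic fits of the same outcome on the same complete-case set
#' and category count — one per SES measure — reports the absolute AIC
#' difference and the maximum relative difference of the non-reference
#' odds ratios, |OR1 - OR2| / OR1.
#'
#' @param fit_a,fit_b [ses_outcome_fit][fit_ses_outcome_model] objects
#'   (the first is the reference for relative OR differences).
#' @return An object of class `ses_outcome_comparison`: `delta_aic`,
#'   `max_relative_or_difference`, `or_table` (side by side), `aic_a`,
#'   `aic_b`, `trend` summaries of both fits.
#' @export
compare_ses_models <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "ses_outcome_fit"),
            inherits(fit_b, "ses_outcome_fit"))
  if (fit_a$n != fit_b$n) {
    stop_ses("fits use different complete-case sets (n = ", fit_a$n,
             " vs ", fit_b$n, ")", class = "outcome_error")
  }
  if (fit_a$k != fit_b$k) {
    stop_ses("fits use different category counts", class = "outcome_error")
  }
  rel <- abs(fit_a$or_table$or[-1L] - fit_b$or_table$or[-1L]) /
    fit_a$or_table$or[-1L]
  structure(list(
    delta_aic = abs(fit_a$aic - fit_b$aic),
    max_relative_or_difference = max(rel),
    aic_a = fit_a$aic, aic_b = fit_b$aic,
    or_table = data.frame(category = fit_a$or_table$category,
                          or_a = fit_a$or_table$or,
                          or_b = fit_b$or_table$or),
    trend = data.frame(measure = c("a", "b"),
                       trend_or = c(fit_a$trend_or, fit_b$trend_or),
                       trend_p = c(fit_a$trend_p, fit_b$trend_p),
                       monotone = c(fit_a$trend_monotone,
                                    fit_b$trend_monotone))
  ), class = "ses_outcome_comparison")
}

#' @export
print.ses_outcome_comparison <- function(x, ...) {
  cat("<ses_outcome_comparison> delta AIC = ",
      sprintf("%.2f", x$delta_aic), "; max relative OR difference = ",
      sprintf("%.1f%%", 100 * x$max_relative_or_difference), "\n", sep = "")
  invisible(x)
}
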