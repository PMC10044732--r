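#' Score the improved water and sanitation component
#'
#' Improved drinking-water source and improved sanitation facility are
#' considered independently and worth 4 points each, summed to 0-8.
#'
#' @param water_improved,sanitation_improved Logical flags (no missing
#'   values allowed).
#' @return Integer vector in 0, 4, 8.
#' @export
score_water_sanitation <- function(water_improved, sanitation_improved) {
  if (anyNA(water_improved)) {
    stop_ses("water_improved is missing", class = "wami_scoring_error")
  }
  if (anyNA(sanitation_improved)) {
    stop_ses("sanitation_improved is missing", class = "wami_scoring_error")
  }
  4L * as.integer(water_improved) + 4L * as.integer(sanitation_improved)
}

#' Assign a value to one of 9 equal intervals over a range
#'
#' Splits `[range_min, range_max]` into 9 equal-width intervals,
#' left-closed/right-open with the last interval closed at `range_max`,
#' and returns the 0-based index of the interval containing `value`.
#' Values outside the range are clamped to 0 or 8 with a warning (this
#' happens when a fitted scaler is applied to new data).
#'
#' @param value Numeric vector.
#' @param range_min,range_max Range endpoints, `range_max > range_min`.
#' @return Integer vector in 0..8.
#' @export
assign_interval_score <- function(value, range_min, range_max) {
  if (!is.finite(range_min) || !is.finite(range_max) ||
      range_max <= range_min) {
    stop_ses("degenerate range [", range_min, ", ", range_max, "]",
             class = "wami_scoring_error")
  }
  if (any(value < range_min | value > range_max, na.rm = TRUE)) {
    warning("values outside [", range_min, ", ", range_max,
            "] clamped to the boundary score")
  }
  idx <- floor((value - range_min) / (range_max - range_min) * 9)
  as.integer(pmin(pmax(idx, 0), 8))
}

#' Fit the PCA asset model on a cohort
#'
#' Performs principal component analysis on the correlation matrix of the
#' 15 binary asset-ownership indicators and retains the first component.
#' Constant (zero-variance) asset columns carry no correlation information
#' and are dropped with a warning. The component is oriented so that the
#' per-participant score correlates positively with the number of assets
#' owned (ties broken toward +1), and the per-participant score range in
#' the fitting cohort is stored so new records can be scored on the same
#' 0-8 interval scale.
#'
#' @param cohort A [ses_cohort][as_cohort]; rows with any missing asset
#'   indicator are excluded from the fit.
#' @return An object of class `wami_asset_model` with elements
#'   `asset_names`, `column_means`, `column_sds`, `loadings`,
#'   `variance_explained_share`, `score_range`, `orientation_sign`.
#' @export
fit_asset_model <- function(cohort) {
  X <- as.matrix(as.data.frame(cohort)[, asset_columns()])
  X <- X[stats::complete.cases(X), , drop = FALSE] * 1
  colnames(X) <- wami_asset_names()
  sds <- apply(X, 2, stats::sd)
  constant <- sds == 0 | is.na(sds)
  if (all(constant)) {
    stop_ses("all asset columns are constant; no correlation structure",
             class = "wami_model_error")
  }
  if (any(constant)) {
    warning("dropping constant asset column(s): ",
            paste(colnames(X)[constant], collapse = ", "))
    X <- X[, !constant, drop = FALSE]
    sds <- sds[!constant]
  }
  if (ncol(X) < 2L) {
    stop_ses("need at least 2 non-constant asset columns",
             class = "wami_model_error")
  }
  if (nrow(X) < ncol(X)) {
    stop_ses("need at least as many complete records (", nrow(X),
             ") as retained assets (", ncol(X), ")",
             class = "wami_model_error")
  }
  mns <- colMeans(X)
  eig <- eigen(stats::cor(X), symmetric = TRUE)
  loadings <- eig$vectors[, 1L]
  Z <- scale(X, center = mns, scale = sds)
  scores <- drop(Z %*% loadings)
  sign <- if (stats::cor(scores, rowSums(X)) < 0) -1 else +1
  loadings <- loadings * sign
  scores <- scores * sign
  structure(list(
    asset_names = colnames(X),
    column_means = mns,
    column_sds = sds,
    loadings = stats::setNames(loadings, colnames(X)),
    variance_explained_share = eig$values[1L] / sum(eig$values),
    score_range = range(scores),
    orientation_sign = sign
  ), class = "wami_asset_model")
}

#' @export
print.wami_asset_model <- function(x, ...) {
  cat("<wami_asset_model> ", length(x$asset_names), " assets, PC1 explains ",
      sprintf("%.2f%%", 100 * x$variance_explained_share),
      " of variance\n", sep = "")
  invisible(x)
}

# raw (pre-interval) first-component score for each record
asset_component_score <- function(model, records) {
  X <- as.matrix(as.data.frame(records)[, paste0("asset_", model$asset_names),
                                        drop = FALSE]) * 1
  if (anyNA(X)) {
    stop_ses("missing asset indicator; record not scorable",
             class = "wami_scoring_error")
  }
  Z <- sweep(sweep(X, 2, model$column_means), 2, model$column_sds, "/")
  drop(Z %*% model$loadings)
}

#' Score the asset component (0-8)
#'
#' Computes the participant's oriented first-component score and assigns
#' it to one of 9 equal intervals over the fitting cohort's score range.
#'
#' @param model A [wami_asset_model][fit_asset_model].
#' @param records A cohort or subset of rows with all retained assets
#'   observed.
#' @return Integer vector in 0..8.
#' @export
score_assets <- function(model, records) {
  stopifnot(inherits(model, "wami_asset_model"))
  assign_interval_score(asset_component_score(model, records),
                        model$score_range[1L], model$score_range[2L])
}

#' Fit the education scaler
#'
#' Records the range of effective education years (participant's own years
#' at age 20 or older, guardian/maternal years below 20) over which the
#' 9 equal scoring intervals are laid.
#'
#' @param cohort A [ses_cohort][as_cohort]; rows missing their effective
#'   education field are excluded.
#' @return An object of class `education_scaler` with `range_min`,
#'   `range_max`.
#' @export
fit_education_scaler <- function(cohort) {
  yrs <- effective_education(cohort)
  yrs <- yrs[!is.na(yrs)]
  if (length(yrs) == 0L || max(yrs) <= min(yrs)) {
    stop_ses("cannot fit education scaler: degenerate education range",
             class = "wami_model_error")
  }
  structure(list(range_min = min(yrs), range_max = max(yrs)),
            class = "education_scaler")
}

#' Score the education component (0-8)
#'
#' Uses the participant's own education years at age 20 or older, and the
#' guardian's (maternal) education years below 20 — even when own years
#' are also recorded.
#'
#' @param records A cohort or subset of rows.
#' @param scaler An [education_scaler][fit_education_scaler].
#' @return Integer vector in 0..8.
#' @export
score_education <- function(records, scaler) {
  stopifnot(inherits(scaler, "education_scaler"))
  yrs <- effective_education(records)
  if (anyNA(yrs)) {
    stop_ses("effective education years missing (own years at age >= 20, ",
             "guardian years below 20)", class = "wami_scoring_error")
  }
  assign_interval_score(yrs, scaler$range_min, scaler$range_max)
}

#' Income brackets used in the original survey
#'
#' The realized monthly-income cutpoints (USD) defining the 9 reporting
#' categories: <$100, $100-150, $150-175, $175-200, $200-225, $225-250,
#' $250-324, $324-411, >$411.
#'
#' @return An `income_brackets` object.
#' @export
study_income_brackets <- function() {
  new_income_brackets(c(100, 150, 175, 200, 225, 250, 324, 411))
}

new_income_brackets <- function(cutpoints) {
  if (length(cutpoints) != 8L || is.unsorted(cutpoints)) {
    stop_ses("income brackets need 8 non-decreasing cutpoints",
             class = "wami_model_error")
  }
  structure(list(cutpoints_usd = as.numeric(cutpoints)),
            class = "income_brackets")
}

#' Build income brackets from sampled incomes
#'
#' Places the 8 cutpoints at the 12.5, 25, ..., 87.5 empirical percentiles
#' of a sample of precise monthly incomes, creating 9 categories of equal
#' sample mass.
#'
#' @param sample_incomes Numeric vector of monthly incomes (USD); at least
#'   9 distinct values required.
#' @return An `income_brackets` object.
#' @export
build_income_brackets <- function(sample_incomes) {
  sample_incomes <- sample_incomes[!is.na(sample_incomes)]
  if (length(unique(sample_incomes)) < 9L) {
    stop_ses("need at least 9 distinct incomes to place 12.5% percentile ",
             "cutpoints", class = "wami_model_error")
  }
  cuts <- unname(stats::quantile(sample_incomes, probs = (1:8) * 0.125,
                                 type = 7))
  new_income_brackets(cuts)
}

#' Score the income component (0-8)
#'
#' A reported bracket index (0-8) passes through unchanged; otherwise the
#' raw monthly USD income is assigned to a bracket, with a value equal to
#' a cutpoint falling in the higher bracket (matching the "<$100" /
#' "$100-150" category labels).
#'
#' @param records A cohort or subset of rows.
#' @param brackets An [income_brackets][build_income_brackets].
#' @return Integer vector in 0..8.
#' @export
score_income <- function(records, brackets) {
  stopifnot(inherits(brackets, "income_brackets"))
  bracket <- records$income_bracket
  usd <- records$income_usd_month
  if (any(is.na(bracket) & is.na(usd))) {
    stop_ses("neither income_bracket nor income_usd_month present",
             class = "wami_scoring_error")
  }
  from_usd <- findInterval(usd, brackets$cutpoints_usd, left.open = FALSE)
  as.integer(ifelse(is.na(bracket), from_usd, bracket))
}

#' Compute WAMI scores for a cohort
#'
#' Fits the asset model and education scaler on the scorable subset of the
#' cohort (see [validate_cohort()]), then scores every scorable record on
#' the four 0-8 components and sums them to the 0-32 total. Deterministic
#' given the cohort.
#'
#' @param cohort A [ses_cohort][as_cohort].
#' @param brackets Optional [income_brackets][build_income_brackets]. When
#'   `NULL`, reported bracket indices are used as-is and, if any scorable
#'   record lacks one, brackets are built from the cohort's raw incomes
#'   via [build_income_brackets()].
#' @return An object of class `wami_result`: `scores` (data frame with
#'   `participant_id`, the four components and `total`), `asset_model`,
#'   `education_scaler`, `brackets`, `scorable` (logical vector over the
#'   input cohort).
#' @export
compute_wami <- function(cohort, brackets = NULL) {
  stopifnot(inherits(cohort, "ses_cohort"))
  scorable <- wami_scorable(cohort)
  if (!any(scorable)) {
    stop_ses("no scorable records", class = "wami_scoring_error")
  }
  sub <- cohort[scorable, , drop = FALSE]
  asset_model <- fit_asset_model(sub)
  education_scaler <- fit_education_scaler(sub)
  if (is.null(brackets)) {
    brackets <- if (all(!is.na(sub$income_bracket))) {
      study_income_brackets()
    } else {
      build_income_brackets(sub$income_usd_month)
    }
  }
  scores <- data.frame(
    participant_id = sub$participant_id,
    water_sanitation = score_water_sanitation(sub$water_improved,
                                              sub$sanitation_improved),
    assets = score_assets(asset_model, sub),
    education = score_education(sub, education_scaler),
    income = score_income(sub, brackets)
  )
  scores$total <- with(scores, water_sanitation + assets + education + income)
  structure(list(scores = scores, asset_model = asset_model,
                 education_scaler = education_scaler, brackets = brackets,
                 scorable = scorable),
            class = "wami_result")
}

#' @export
print.wami_result <- function(x, ...) {
  cat("<wami_result> ", nrow(x$scores), " scored participants; total ",
      "median ", stats::median(x$scores$total), " (range ",
      min(x$scores$total), "-", max(x$scores$total), ")\n", sep = "")
  invisible(x)
}
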