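#' Configure a full comparison pipeline run
#'
#' Bundles every knob of the end-to-end pipeline (score, rescale,
#' agreement, Bland-Altman, retest substitution, outcome models) into one
#' validated object. Exactly one input source is used: a cohort file path,
#' an in-memory cohort, or a synthetic-cohort configuration.
#'
#' @param input A file path, a [ses_cohort][as_cohort], or a
#'   [ses_synth_config][default_config].
#' @param out_dir Output directory for the report tables (created if
#'   missing).
#' @param ks Agreement category scales (default 10, 5, 4, 3).
#' @param ba_mode,ba_percentile Bland-Altman outlier rule (see
#'   [bland_altman()]).
#' @param retest `NULL` to skip the retest stage, otherwise a list with
#'   `n_outliers` (default 14) and `n_controls` (default 22).
#' @param outcome_ks Category counts for the SES/asthma logistic models
#'   (`NULL` skips the stage).
#' @param seed Master seed; stage sub-streams are derived from it.
#' @return An object of class `ses_pipeline_config`.
#' @export
pipeline_config <- function(input, out_dir = tempfile("sesagree_"),
                            ks = c(10L, 5L, 4L, 3L),
                            ba_mode = c("absolute", "two_sided"),
                            ba_percentile = 95,
                            retest = list(n_outliers = 14L, n_controls = 22L),
                            outcome_ks = 3L, seed = 1L) {
  ba_mode <- match.arg(ba_mode)
  sources <- inherits(input, "ses_cohort") + inherits(input, "ses_synth_config") +
    (is.character(input) && length(input) == 1L)
  if (sources != 1L) {
    stop_ses("input must be exactly one of: path, ses_cohort, ",
             "ses_synth_config", class = "pipeline_error")
  }
  structure(list(input = input, out_dir = out_dir, ks = as.integer(ks),
                 ba_mode = ba_mode, ba_percentile = ba_percentile,
                 retest = retest, outcome_ks = outcome_ks,
                 seed = as.integer(seed)),
            class = "ses_pipeline_config")
}

write_tsv <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "")
  path
}

#' Run the full WAMI-vs-ladder comparison pipeline
#'
#' Executes, in order: cohort acquisition (read, use as-is, or generate),
#' validation, WAMI scoring, cohort summary, the agreement table across
#' category scales, Bland-Altman outlier identification on the common
#' 10-point scale, optional retest substitution with before/after
#' agreement, and optional age/gender-adjusted asthma models per SES
#' measure compared by AIC. Every table is written as delimited text into
#' `config$out_dir` along with a JSON model file and a plain-text log that
#' records each convention in effect (cutpoints, Bland-Altman mode and
#' percentile estimator), so runs are auditable. Deterministic given the
#' master seed.
#'
#' @param config A [ses_pipeline_config][pipeline_config].
#' @return Invisibly, the report bundle: `cohort`, `validation`, `wami`,
#'   `summary`, `agreement`, `ba`, `retest` (or `NULL`), `outcome` (or
#'   `NULL`), `paths` of the written files.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "ses_pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  note <- function(...) log_lines <<- c(log_lines, paste0(...))

  # --- input stage ---------------------------------------------------
  truth <- NULL
  cohort <- if (inherits(config$input, "ses_cohort")) {
    note("input: in-memory cohort (", nrow(config$input), " records)")
    config$input
  } else if (inherits(config$input, "ses_synth_config")) {
    gen_cfg <- config$input
    gen_cfg$seed <- derive_seed(config$seed, 100L)
    note("input: synthetic cohort, n = ", gen_cfg$n,
         ", generator seed = ", gen_cfg$seed)
    gen <- generate_cohort(gen_cfg)
    truth <- gen$truth
    gen$cohort
  } else {
    note("input: file ", config$input)
    read_cohort(config$input)
  }
  validation <- validate_cohort(cohort)

  # --- WAMI scoring --------------------------------------------------
  wami <- compute_wami(cohort)
  note("income brackets (USD cutpoints): ",
       paste(wami$brackets$cutpoints_usd, collapse = ", "))
  note(sprintf("asset PC1 variance share: %.4f",
               wami$asset_model$variance_explained_share))

  summary_tab <- cohort_summary(cohort, wami)

  # --- agreement -----------------------------------------------------
  agreement <- agreement_suite(cohort, wami, config$ks)
  for (k in names(attr(agreement, "schemes"))) {
    sch <- attr(agreement, "schemes")[[k]]
    note(k, " wami cutpoints: ", paste(sch$wami$cutpoints, collapse = ", "),
         if (!is.null(sch$ladder)) paste0("; ladder cutpoints: ",
                                          paste(sch$ladder$cutpoints,
                                                collapse = ", ")))
  }
  ba <- ba_on_common_scale(cohort, wami, config$ba_mode, config$ba_percentile)
  note("bland-altman: mode = ", config$ba_mode, ", percentile = ",
       config$ba_percentile,
       " (linear-interpolation/type-7 estimator); outliers = ",
       ba$outlier_count, " (", sprintf("%.1f%%", 100 * ba$outlier_fraction),
       ")")

  # --- retest stage (optional) --------------------------------------
  retest <- NULL
  if (!is.null(config$retest)) {
    ids <- attr(ba, "participant_ids")
    has_rt <- !is.na(cohort$ladder_retest[match(ids, cohort$participant_id)])
    n_out <- min(config$retest$n_outliers %||% 14L,
                 sum(ba$outlier_flags & has_rt))
    n_ctl <- min(config$retest$n_controls %||% 22L,
                 sum(!ba$outlier_flags & has_rt))
    if (n_out < (config$retest$n_outliers %||% 14L)) {
      note("retest: outlier sample capped at the ", n_out,
           " retestable outliers available")
    }
    plan <- select_retest_sample(ba, cohort, ids, n_outliers = n_out,
                                 n_controls = n_ctl,
                                 seed = derive_seed(config$seed, 200L))
    retest <- retest_comparison(cohort, wami, plan, config$ks,
                                ba_mode = config$ba_mode,
                                percentile = config$ba_percentile)
    note("retest: substituted ", length(plan$outlier_ids), " outliers + ",
         length(plan$control_ids), " controls; outliers ",
         retest$outliers_before, " -> ", retest$outliers_after)
  }

  # --- outcome stage (optional) -------------------------------------
  outcome <- NULL
  if (!is.null(config$outcome_ks)) {
    outcome <- lapply(config$outcome_ks, function(k) {
      cats <- ses_categories_for(cohort, wami, k)
      fw <- fit_ses_outcome_model(cohort, cats$wami)
      fl <- fit_ses_outcome_model(cohort, cats$ladder)
      cmp <- compare_ses_models(fw, fl)
      note("outcome k = ", k, ": AIC wami = ", sprintf("%.2f", fw$aic),
           ", ladder = ", sprintf("%.2f", fl$aic), ", delta = ",
           sprintf("%.2f", cmp$delta_aic))
      list(k = k, wami = fw, ladder = fl, comparison = cmp)
    })
    names(outcome) <- paste0("k", config$outcome_ks)
  }

  # --- write the bundle ---------------------------------------------
  paths <- c(
    cohort = write_tsv(as.data.frame(lapply(as.data.frame(cohort), function(c)
      if (is.logical(c)) as.integer(c) else c)), config$out_dir, "cohort.tsv"),
    summary = write_tsv(summary_tab, config$out_dir, "cohort_summary.tsv"),
    validation = write_tsv(validation, config$out_dir, "validation.tsv"),
    agreement = write_tsv(format_agreement(agreement), config$out_dir,
                          "agreement.tsv"),
    outliers = write_tsv(
      data.frame(participant_id = attr(ba, "participant_ids"),
                 mean = ba$mean, diff = ba$diff,
                 outlier = as.integer(ba$outlier_flags)),
      config$out_dir, "bland_altman.tsv")
  )
  if (!is.null(truth)) {
    paths["truth"] <- write_tsv(truth, config$out_dir, "truth.tsv")
  }
  if (!is.null(retest)) {
    combined <- cbind(format_agreement(retest$after),
                      retest$delta[, c("delta_rho", "delta_kappa")])
    paths["retest"] <- write_tsv(combined, config$out_dir,
                                 "retest_agreement.tsv")
  }
  if (!is.null(outcome)) {
    rows <- do.call(rbind, lapply(outcome, function(o) {
      data.frame(k = o$k,
                 measure = rep(c("wami", "ladder"), each = o$k),
                 category = c(o$wami$or_table$category,
                              o$ladder$or_table$category),
                 or = sprintf("%.4f", c(o$wami$or_table$or,
                                        o$ladder$or_table$or)),
                 ci_low = sprintf("%.4f", c(o$wami$or_table$ci_low,
                                            o$ladder$or_table$ci_low)),
                 ci_high = sprintf("%.4f", c(o$wami$or_table$ci_high,
                                             o$ladder$or_table$ci_high)),
                 aic = sprintf("%.4f", rep(c(o$wami$aic, o$ladder$aic),
                                           each = o$k)))
    }))
    paths["outcome"] <- write_tsv(rows, config$out_dir, "outcome.tsv")
  }
  models <- list(asset_model = wami$asset_model,
                 education_scaler = wami$education_scaler,
                 brackets = wami$brackets)
  paths["models"] <- file.path(config$out_dir, "models.json")
  write_model(models, paths[["models"]])
  paths["log"] <- file.path(config$out_dir, "log.txt")
  writeLines(log_lines, paths[["log"]])

  invisible(list(cohort = cohort, truth = truth, validation = validation,
                 wami = wami, summary = summary_tab, agreement = agreement,
                 ba = ba, retest = retest, outcome = outcome, paths = paths,
                 log = log_lines))
}

format_agreement <- function(agreement) {
  data.frame(scale = agreement$scale, k = agreement$k, n = agreement$n,
             rho = sprintf("%.4f", agreement$rho),
             kappa = ifelse(is.na(agreement$kappa), "",
                            sprintf("%.4f", agreement$kappa)),
             kappa_label = ifelse(is.na(agreement$kappa_label), "",
                                  agreement$kappa_label))
}

# SES category vectors (aligned to cohort rows, NA where unscorable) for
# the outcome models: WAMI totals and ladder both rescaled to k categories
ses_categories_for <- function(cohort, wami, k) {
  pairs <- agreement_pairs(cohort, wami)
  ws <- build_rescale_scheme(pairs$wami, k, source_label = "wami_total")
  ls <- if (k == 10L) NULL else
    build_rescale_scheme(pairs$ladder, k, source_label = "ladder")
  idx <- match(pairs$participant_id, cohort$participant_id)
  wami_cat <- rep(NA_integer_, nrow(cohort))
  ladder_cat <- rep(NA_integer_, nrow(cohort))
  wami_cat[idx] <- apply_rescale(pairs$wami, ws)
  ladder_cat[idx] <- if (is.null(ls)) pairs$ladder else
    apply_rescale(pairs$ladder, ls)
  list(wami = wami_cat, ladder = ladder_cat)
}

# Table-1-style long-format cohort description
cohort_summary <- function(cohort, wami = NULL) {
  qs <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE,
                                    type = 7)
  stat <- function(name, value) data.frame(statistic = name,
                                           value = as.character(value))
  pct <- function(x) sprintf("%.1f%%", 100 * mean(x, na.rm = TRUE))
  aq <- qs(cohort$age)
  lq <- qs(cohort$ladder)
  eq <- qs(effective_education(cohort))
  inc_grp <- findInterval(cohort$income_bracket, c(5, 7)) + 1L
  rows <- list(
    stat("n", nrow(cohort)),
    stat("female", pct(cohort$gender == "female")),
    stat("age median (IQR)", sprintf("%g (%g-%g)", aq[2], aq[1], aq[3])),
    stat("improved drinking water", pct(cohort$water_improved)),
    stat("improved sanitation", pct(cohort$sanitation_improved)),
    stat("education years median (IQR)",
         sprintf("%g (%g-%g)", eq[2], eq[1], eq[3])),
    stat("income < $224", pct(inc_grp == 1)),
    stat("income $224-324", pct(inc_grp == 2)),
    stat("income > $324", pct(inc_grp == 3)),
    stat("ladder median (IQR)", sprintf("%g (%g-%g)", lq[2], lq[1], lq[3]))
  )
  for (a in wami_asset_names()) {
    rows[[length(rows) + 1L]] <- stat(paste0("asset: ", a),
                                      pct(cohort[[paste0("asset_", a)]]))
  }
  if (!is.null(wami)) {
    wq <- qs(wami$scores$total)
    rows[[length(rows) + 1L]] <-
      stat("wami total median (IQR)", sprintf("%g (%g-%g)", wq[2], wq[1], wq[3]))
  }
  do.call(rbind, rows)
}
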