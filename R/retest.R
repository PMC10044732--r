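#' Select participants for the ladder retest
#'
#' Draws `n_outliers` participants from those flagged by a Bland-Altman
#' analysis and `n_controls` from those not flagged, restricted to
#' participants with a retest ladder score. The draw is deterministic
#' given the seed.
#'
#' @param ba A [bland_altman] result computed on the cohort's
#'   agreement-complete records, with `participant_ids` attribute or with
#'   flags aligned to `ids`.
#' @param cohort The [ses_cohort][as_cohort] the analysis was computed on.
#' @param ids Participant ids aligned with `ba`'s flags.
#' @param n_outliers,n_controls How many of each group to select.
#' @param seed Integer seed for the draw.
#' @return An object of class `retest_plan`: `outlier_ids`, `control_ids`.
#' @export
select_retest_sample <- function(ba, cohort, ids, n_outliers, n_controls,
                                 seed) {
  stopifnot(inherits(ba, "bland_altman"), inherits(cohort, "ses_cohort"),
            length(ids) == ba$n)
  has_retest <- !is.na(cohort$ladder_retest[match(ids, cohort$participant_id)])
  out_pool <- ids[ba$outlier_flags & has_retest]
  ctl_pool <- ids[!ba$outlier_flags & has_retest]
  if (n_outliers > length(out_pool)) {
    stop_ses("requested ", n_outliers, " outliers but only ",
             length(out_pool), " retestable outliers exist",
             class = "retest_error")
  }
  if (n_controls > length(ctl_pool)) {
    stop_ses("requested ", n_controls, " controls but only ",
             length(ctl_pool), " retestable non-outliers exist",
             class = "retest_error")
  }
  plan <- with_seed(seed, {
    list(
      outlier_ids = if (n_outliers > 0) sample(out_pool, n_outliers) else character(0),
      control_ids = if (n_controls > 0) sample(ctl_pool, n_controls) else character(0)
    )
  })
  structure(plan, class = "retest_plan")
}

#' Write or read a retest plan as two-column id/role text
#'
#' @param plan A [retest_plan][select_retest_sample].
#' @param path File path.
#' @return `write_retest_plan()` invisibly returns the path;
#'   `read_retest_plan()` returns the plan.
#' @export
write_retest_plan <- function(plan, path) {
  stopifnot(inherits(plan, "retest_plan"))
  df <- data.frame(
    participant_id = c(plan$outlier_ids, plan$control_ids),
    role = rep(c("outlier", "control"),
               c(length(plan$outlier_ids), length(plan$control_ids))))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_retest_plan
#' @export
read_retest_plan <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("participant_id", "role") %in% names(df)) ||
      !all(df$role %in% c("outlier", "control"))) {
    stop_ses("not a retest plan file: ", path, class = "retest_error")
  }
  structure(list(
    outlier_ids = df$participant_id[df$role == "outlier"],
    control_ids = df$participant_id[df$role == "control"]
  ), class = "retest_plan")
}

#' @export
print.retest_plan <- function(x, ...) {
  cat("<retest_plan> ", length(x$outlier_ids), " outliers + ",
      length(x$control_ids), " controls\n", sep = "")
  invisible(x)
}

#' Substitute retest ladder scores for planned participants
#'
#' Returns a copy of the cohort in which `ladder` is replaced by
#' `ladder_retest` for exactly the participants in the plan; every other
#' field (including `ladder_retest` itself) is untouched, so the
#' substitution is idempotent.
#'
#' @param cohort A [ses_cohort][as_cohort].
#' @param plan A [retest_plan][select_retest_sample].
#' @return The substituted cohort.
#' @export
substitute_retest <- function(cohort, plan) {
  stopifnot(inherits(cohort, "ses_cohort"), inherits(plan, "retest_plan"))
  ids <- c(plan$outlier_ids, plan$control_ids)
  if (length(ids) == 0L) return(cohort)
  idx <- match(ids, cohort$participant_id)
  if (anyNA(idx)) {
    stop_ses("plan ids not in cohort: ",
             paste(ids[is.na(idx)], collapse = ", "), class = "retest_error")
  }
  if (anyNA(cohort$ladder_retest[idx])) {
    stop_ses("planned participant(s) lack a retest ladder score",
             class = "retest_error")
  }
  cohort$ladder[idx] <- cohort$ladder_retest[idx]
  cohort
}

#' Before/after comparison of agreement under retest substitution
#'
#' Computes the agreement table and the 10-point Bland-Altman outlier
#' analysis before and after replacing the planned participants' initial
#' ladder scores with their retest scores, and reports the change in rho,
#' kappa and outlier count. WAMI scores are unchanged by the substitution.
#' By default the Bland-Altman percentile threshold is recomputed on the
#' substituted cohort; `freeze_threshold = TRUE` keeps the original
#' threshold instead.
#'
#' @param cohort A [ses_cohort][as_cohort].
#' @param wami A [wami_result][compute_wami] (computed when `NULL`).
#' @param plan A [retest_plan][select_retest_sample].
#' @param ks Category counts for the agreement table.
#' @param ba_mode,percentile Passed to [bland_altman()].
#' @param freeze_threshold Keep the pre-substitution outlier threshold.
#' @return An object of class `retest_comparison`: `before`, `after`
#'   (agreement tables), `delta` (per-scale changes), `ba_before`,
#'   `ba_after`, `outliers_before`, `outliers_after`.
#' @export
retest_comparison <- function(cohort, wami = NULL, plan,
                              ks = c(10L, 5L, 4L, 3L),
                              ba_mode = c("absolute", "two_sided"),
                              percentile = 95, freeze_threshold = FALSE) {
  ba_mode <- match.arg(ba_mode)
  stopifnot(inherits(plan, "retest_plan"))
  if (is.null(wami)) wami <- compute_wami(cohort)
  after_cohort <- substitute_retest(cohort, plan)

  before <- agreement_suite(cohort, wami, ks)
  after <- agreement_suite(after_cohort, wami, ks)

  ba_before <- ba_on_common_scale(cohort, wami, ba_mode, percentile)
  ba_after <- ba_on_common_scale(after_cohort, wami, ba_mode, percentile,
                                 threshold = if (freeze_threshold)
                                   ba_before$outlier_threshold else NULL)

  delta <- data.frame(scale = before$scale, k = before$k,
                      delta_rho = after$rho - before$rho,
                      delta_kappa = after$kappa - before$kappa)
  structure(list(before = before, after = after, delta = delta,
                 ba_before = ba_before, ba_after = ba_after,
                 outliers_before = ba_before$outlier_count,
                 outliers_after = ba_after$outlier_count,
                 plan = plan),
            class = "retest_comparison")
}

#' @export
print.retest_comparison <- function(x, ...) {
  cat("<retest_comparison> outliers ", x$outliers_before, " -> ",
      x$outliers_after, "\n", sep = "")
  print(x$delta)
  invisible(x)
}

# Bland-Altman of the 10-category WAMI against the 10-point ladder,
# optionally with a frozen outlier threshold
ba_on_common_scale <- function(cohort, wami, mode = "absolute",
                               percentile = 95, threshold = NULL) {
  pairs <- agreement_pairs(cohort, wami)
  wami10 <- rescale_wami_to_10(pairs$wami)$categories
  ba <- bland_altman(wami10, pairs$ladder, percentile = percentile,
                     mode = mode, k_x = 10L, k_y = 10L)
  if (!is.null(threshold)) {
    if (ba$mode == "absolute") {
      ba$outlier_flags <- abs(ba$diff) > threshold
    } else {
      ba$outlier_flags <- ba$diff < threshold[1L] | ba$diff > threshold[2L]
    }
    ba$outlier_threshold <- threshold
    ba$outlier_count <- sum(ba$outlier_flags)
    ba$outlier_fraction <- mean(ba$outlier_flags)
  }
  attr(ba, "participant_ids") <- pairs$participant_id
  ba
}
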