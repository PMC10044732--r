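#' The 15 surveyed household assets
#'
#' Ordered names of the durable assets whose binary ownership indicators
#' enter the WAMI asset component: iron (charcoal or electric), bed, chair
#' or bench, sofa, cupboard, table, electric fan, radio or transistor,
#' computer, television, mobile phone, refrigerator, watch or clock, bike,
#' bank account. Cohort tables store them as columns `asset_<name>`.
#'
#' @return Character vector of length 15.
#' @export
wami_asset_names <- function() {
  c("iron", "bed", "chair_or_bench", "sofa", "cupboard", "table",
    "electric_fan", "radio", "computer", "television", "mobile_phone",
    "refrigerator", "watch_or_clock", "bike", "bank_account")
}

asset_columns <- function() paste0("asset_", wami_asset_names())

cohort_columns <- function() {
  c("participant_id", "age", "gender", "education_years",
    "guardian_education_years", "water_improved", "sanitation_improved",
    asset_columns(), "income_usd_month", "income_bracket", "ladder",
    "ladder_retest", "asthma_history")
}

#' Construct a survey cohort
#'
#' A cohort is a data frame with one row per participant and the canonical
#' survey columns (see [wami_asset_names()] for asset columns), carrying a
#' provenance label and a currency conversion rate as attributes. Records
#' are validated against the row-level invariants (age at least 14, ladder
#' scores in 1..10, income bracket in 0..8, non-negative education years
#' and income, unique participant ids).
#'
#' @param records Data frame with the canonical columns; missing optional
#'   columns are added as `NA`.
#' @param provenance Free-text label describing where the records came from.
#' @param currency_rate Soles-to-USD conversion rate, default 0.25
#'   (1 Peruvian Sol = 0.25 USD).
#' @param strict `"reject"` stops on any invalid row; `"drop"` removes
#'   invalid rows with a message and attaches the issue table as the
#'   `"issues"` attribute.
#' @return An object of class `ses_cohort` (a data frame).
#' @export
as_cohort <- function(records, provenance = "unspecified",
                      currency_rate = 0.25, strict = c("reject", "drop")) {
  strict <- match.arg(strict)
  stopifnot(is.data.frame(records), currency_rate > 0)
  for (col in setdiff(cohort_columns(), names(records))) {
    records[[col]] <- if (col %in% c("gender")) NA_character_ else NA
  }
  records <- records[, cohort_columns()]
  records$participant_id <- as.character(records$participant_id)

  issues <- validate_records(records)
  if (nrow(issues) > 0L) {
    if (strict == "reject") {
      stop_ses("invalid records: ",
               paste0("row ", issues$row, " [", issues$field, "] ",
                      issues$reason, collapse = "; "),
               class = "cohort_validation_error")
    }
    drop <- unique(issues$row)
    message(length(drop), " record(s) dropped; see attr(, 'issues')")
    records <- records[-drop, , drop = FALSE]
    rownames(records) <- NULL
  }
  if (anyDuplicated(records$participant_id)) {
    stop_ses("participant_id values must be unique",
             class = "cohort_validation_error")
  }
  structure(records,
            provenance = provenance,
            currency_rate = currency_rate,
            issues = issues,
            class = c("ses_cohort", "data.frame"))
}

# row-level invariant checks; returns a data.frame(row, field, reason)
validate_records <- function(records) {
  issues <- list()
  flag <- function(rows, field, reason) {
    if (any(rows)) {
      issues[[length(issues) + 1L]] <<-
        data.frame(row = which(rows), field = field, reason = reason)
    }
  }
  in_range <- function(x, lo, hi) !is.na(x) & (x < lo | x > hi | x != round(x))

  flag(is.na(records$participant_id) | records$participant_id == "",
       "participant_id", "missing id")
  flag(is.na(records$age) | records$age < 14, "age",
       "age must be present and at least 14")
  flag(!is.na(records$gender) & !records$gender %in% c("female", "male"),
       "gender", "gender must be 'female' or 'male'")
  flag(in_range(records$ladder, 1, 10), "ladder",
       "ladder must be an integer in 1..10")
  flag(in_range(records$ladder_retest, 1, 10), "ladder_retest",
       "ladder_retest must be an integer in 1..10")
  flag(in_range(records$income_bracket, 0, 8), "income_bracket",
       "income_bracket must be an integer in 0..8")
  flag(!is.na(records$income_usd_month) & records$income_usd_month < 0,
       "income_usd_month", "income must be non-negative")
  flag(!is.na(records$education_years) & records$education_years < 0,
       "education_years", "education years must be non-negative")
  flag(!is.na(records$guardian_education_years) &
         records$guardian_education_years < 0,
       "guardian_education_years", "education years must be non-negative")

  if (length(issues) == 0L) {
    return(data.frame(row = integer(), field = character(),
                      reason = character()))
  }
  out <- do.call(rbind, issues)
  out[order(out$row), , drop = FALSE]
}

#' @export
print.ses_cohort <- function(x, ...) {
  cat("<ses_cohort> ", nrow(x), " participants  (provenance: ",
      attr(x, "provenance"), ")\n", sep = "")
  print(utils::head(as.data.frame(x), 5L))
  if (nrow(x) > 5L) cat("... ", nrow(x) - 5L, " more rows\n", sep = "")
  invisible(x)
}

parse_flag <- function(x, field) {
  if (is.logical(x)) return(x)
  s <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(s))
  out[s %in% c("1", "true", "yes", "t")] <- TRUE
  out[s %in% c("0", "false", "no", "f")] <- FALSE
  bad <- !is.na(s) & s != "" & is.na(out)
  if (any(bad)) {
    stop_ses("unparseable boolean in '", field, "' (rows ",
             paste(which(bad), collapse = ","), ")",
             class = "cohort_parse_error")
  }
  out
}

parse_num <- function(x, field) {
  if (is.numeric(x)) return(x)
  s <- trimws(as.character(x))
  s[s == ""] <- NA
  out <- suppressWarnings(as.numeric(s))
  bad <- !is.na(s) & is.na(out)
  if (any(bad)) {
    stop_ses("unparseable number in '", field, "' (rows ",
             paste(which(bad), collapse = ","), ")",
             class = "cohort_parse_error")
  }
  out
}

#' Read a survey cohort from delimited text
#'
#' Reads a CSV or TSV file (delimiter autodetected from the header line
#' unless given) with one header row and one row per participant. Header
#' names are matched case-insensitively; a user alias map can rename
#' nonstandard headers onto the canonical ones. A column
#' `income_soles_month` is converted to USD with `currency_rate` on read.
#'
#' @param path Path to the delimited text file.
#' @param delimiter Field delimiter; `NULL` autodetects tab vs comma.
#' @param aliases Named character vector mapping file headers to canonical
#'   column names, e.g. `c(sex = "gender")`.
#' @param strict `"reject"` (fail the whole file on any invalid row) or
#'   `"drop"` (drop invalid rows, reported via the `"issues"` attribute).
#' @param currency_rate Soles-to-USD rate used for `income_soles_month`.
#' @param provenance Label stored on the cohort; defaults to the file name.
#' @return A [ses_cohort][as_cohort] object.
#' @export
read_cohort <- function(path, delimiter = NULL, aliases = NULL,
                        strict = c("reject", "drop"), currency_rate = 0.25,
                        provenance = basename(path)) {
  strict <- match.arg(strict)
  if (!file.exists(path)) {
    stop_ses("file not found: ", path, class = "cohort_io_error")
  }
  if (is.null(delimiter)) {
    header <- readLines(path, n = 1L)
    delimiter <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = delimiter,
                           stringsAsFactors = FALSE, quote = "\"",
                           na.strings = c("", "NA"), check.names = FALSE,
                           colClasses = "character", encoding = "UTF-8")
  names(raw) <- tolower(trimws(names(raw)))
  if (!is.null(aliases)) {
    hit <- match(tolower(names(aliases)), names(raw))
    names(raw)[hit[!is.na(hit)]] <- unname(aliases)[!is.na(hit)]
  }

  mandatory <- c("participant_id", "age", "gender", "water_improved",
                 "sanitation_improved", asset_columns(), "ladder")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols) > 0L) {
    stop_ses("missing mandatory column(s): ",
             paste(missing_cols, collapse = ", "),
             class = "cohort_schema_error")
  }

  df <- data.frame(participant_id = as.character(raw$participant_id),
                   stringsAsFactors = FALSE)
  df$age <- parse_num(raw$age, "age")
  df$gender <- tolower(as.character(raw$gender))
  for (col in c("education_years", "guardian_education_years",
                "income_usd_month", "income_bracket", "ladder",
                "ladder_retest")) {
    df[[col]] <- if (col %in% names(raw)) parse_num(raw[[col]], col) else NA_real_
  }
  if ("income_soles_month" %in% names(raw)) {
    soles <- parse_num(raw$income_soles_month, "income_soles_month")
    usd <- soles * currency_rate
    df$income_usd_month <- ifelse(is.na(df$income_usd_month), usd,
                                  df$income_usd_month)
  }
  for (col in c("water_improved", "sanitation_improved", asset_columns(),
                "asthma_history")) {
    df[[col]] <- if (col %in% names(raw)) parse_flag(raw[[col]], col) else NA
  }
  as_cohort(df, provenance = provenance, currency_rate = currency_rate,
            strict = strict)
}

#' Write a cohort to delimited text
#'
#' Writes the canonical columns as UTF-8 delimited text with one header
#' row. Logical indicators are written as 0/1 and missing values as empty
#' cells, so that [read_cohort()] round-trips to an equal cohort.
#'
#' @param cohort A [ses_cohort][as_cohort].
#' @param path Output path.
#' @param delimiter Field delimiter (default tab).
#' @return Invisibly, the path.
#' @export
write_cohort <- function(cohort, path, delimiter = "\t") {
  stopifnot(inherits(cohort, "ses_cohort"))
  if (nrow(cohort) == 0L) {
    stop_ses("cohort is empty", class = "cohort_io_error")
  }
  out <- as.data.frame(cohort)
  for (col in names(out)) {
    if (is.logical(out[[col]])) out[[col]] <- as.integer(out[[col]])
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = delimiter, row.names = FALSE,
                       quote = FALSE, na = "", fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop_ses("cannot write '", path, "': ", conditionMessage(ok),
             class = "cohort_io_error")
  }
  invisible(path)
}

# which education field each participant's WAMI education component uses:
# own years at age >= 20, guardian (maternal) years below 20
effective_education <- function(cohort) {
  ifelse(cohort$age >= 20, cohort$education_years,
         cohort$guardian_education_years)
}

wami_scorable <- function(cohort) {
  assets_ok <- rowSums(is.na(as.matrix(cohort[, asset_columns()]))) == 0L
  ws_ok <- !is.na(cohort$water_improved) & !is.na(cohort$sanitation_improved)
  edu_ok <- !is.na(effective_education(cohort))
  inc_ok <- !is.na(cohort$income_bracket) | !is.na(cohort$income_usd_month)
  assets_ok & ws_ok & edu_ok & inc_ok
}

#' Count complete-case usable records per analysis
#'
#' Each downstream analysis uses only the records complete for its own
#' inputs (complete-case per analysis; no imputation). This report counts,
#' deterministically, how many records are usable for WAMI scoring,
#' WAMI-vs-ladder agreement, the ladder retest comparison, and the
#' age/gender-adjusted outcome model.
#'
#' @param cohort A [ses_cohort][as_cohort].
#' @return A data frame with one row per analysis: `analysis`, `n_usable`,
#'   `n_total`.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "ses_cohort"))
  wami <- wami_scorable(cohort)
  ladder <- !is.na(cohort$ladder)
  agreement <- wami & ladder
  retest <- ladder & !is.na(cohort$ladder_retest)
  outcome <- agreement & !is.na(cohort$asthma_history) &
    !is.na(cohort$age) & !is.na(cohort$gender)
  data.frame(
    analysis = c("wami_scoring", "agreement", "retest", "outcome_model"),
    n_usable = c(sum(wami), sum(agreement), sum(retest), sum(outcome)),
    n_total = nrow(cohort)
  )
}
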