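# hand-built cohort rows with sensible defaults, overridable per record
make_records <- function(n, ...) {
  assets <- as.data.frame(
    matrix(rep(c(TRUE, FALSE), length.out = n * 15), nrow = n,
           dimnames = list(NULL, paste0("asset_", wami_asset_names()))))
  base <- data.frame(
    participant_id = sprintf("T%03d", seq_len(n)),
    age = 30, gender = "female", education_years = 11,
    guardian_education_years = NA_real_,
    water_improved = TRUE, sanitation_improved = TRUE,
    stringsAsFactors = FALSE)
  base <- cbind(base, assets)
  base$income_usd_month <- 200
  base$income_bracket <- NA_real_
  base$ladder <- 5
  base$ladder_retest <- NA_real_
  base$asthma_history <- FALSE
  overrides <- list(...)
  for (nm in names(overrides)) base[[nm]] <- overrides[[nm]]
  base
}

make_cohort <- function(n, ...) as_cohort(make_records(n, ...))

# a small varied cohort that is scorable end to end
varied_cohort <- function(n = 60, seed = 42) {
  cfg <- default_config(n = n, seed = seed)
  generate_cohort(cfg)$cohort
}

temp_tsv <- function() tempfile(fileext = ".tsv")
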