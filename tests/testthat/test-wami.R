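test_that("water/sanitation component follows the 4-points-each rule", {
  expect_equal(score_water_sanitation(TRUE, TRUE), 8L)
  expect_equal(score_water_sanitation(FALSE, FALSE), 0L)
  expect_equal(score_water_sanitation(TRUE, FALSE), 4L)
  expect_equal(score_water_sanitation(FALSE, TRUE), 4L)
  expect_error(score_water_sanitation(NA, TRUE), "water",
               class = "wami_scoring_error")
})

test_that("interval scores match a brute-force loop over the 9 intervals", {
  expect_equal(assign_interval_score(0, 0, 18), 0L)
  expect_equal(assign_interval_score(18, 0, 18), 8L)
  expect_equal(assign_interval_score(9, 0, 18), 4L)   # 9 in [8, 10)
  set.seed(101)
  for (i in 1:10000) {
    lo <- runif(1, -50, 50)
    hi <- lo + runif(1, 0.1, 100)
    v <- runif(1, lo, hi)
    expect_identical(assign_interval_score(v, lo, hi),
                     interval_oracle(v, lo, hi))
  }
  expect_error(assign_interval_score(1, 2, 2), "degenerate",
               class = "wami_scoring_error")
  expect_warning(out <- assign_interval_score(25, 0, 18), "clamped")
  expect_equal(out, 8L)
})

test_that("duplicated asset indicators receive equal-magnitude loadings", {
  set.seed(7)
  recs <- make_records(200)
  a <- runif(200) < 0.5
  b <- runif(200) < 0.5
  cols <- paste0("asset_", wami_asset_names())
  for (col in cols) recs[[col]] <- runif(200) < 0.5
  recs$asset_iron <- a
  recs$asset_sofa <- a        # exact duplicate of iron
  recs$asset_bike <- b
  recs$asset_computer <- b    # exact duplicate of bike
  model <- fit_asset_model(as_cohort(recs))
  expect_equal(abs(model$loadings[["iron"]]), abs(model$loadings[["sofa"]]),
               tolerance = 1e-8)
  expect_equal(abs(model$loadings[["bike"]]), abs(model$loadings[["computer"]]),
               tolerance = 1e-8)
})

test_that("constant asset columns are dropped, not fatal", {
  recs <- make_records(100)
  set.seed(8)
  for (col in paste0("asset_", wami_asset_names())) {
    recs[[col]] <- runif(100) < 0.5
  }
  recs$asset_bed <- TRUE  # everyone owns a bed
  expect_warning(model <- fit_asset_model(as_cohort(recs)), "bed")
  expect_equal(length(model$asset_names), 14L)
  expect_false("bed" %in% model$asset_names)

  all_const <- make_records(20)
  for (col in paste0("asset_", wami_asset_names())) all_const[[col]] <- TRUE
  expect_error(fit_asset_model(as_cohort(all_const)), "constant",
               class = "wami_model_error")
})

test_that("asset scores are oriented, bounded, and hit 0 and 8 at the extremes", {
  set.seed(9)
  recs <- make_records(150)
  z <- rnorm(150)  # shared wealth axis so every loading is positive
  for (col in paste0("asset_", wami_asset_names())) {
    recs[[col]] <- (z + rnorm(150)) > 0
  }
  # force an owns-everything and an owns-nothing participant
  for (col in paste0("asset_", wami_asset_names())) {
    recs[[col]][1] <- TRUE
    recs[[col]][2] <- FALSE
  }
  co <- as_cohort(recs)
  model <- fit_asset_model(co)
  scores <- score_assets(model, co)
  expect_true(all(scores >= 0L & scores <= 8L))
  expect_equal(scores[1], 8L)
  expect_equal(scores[2], 0L)
  # orientation invariant: component score correlates positively with count
  raw <- sesagree:::asset_component_score(model, co)
  counts <- rowSums(as.matrix(as.data.frame(co)[, paste0("asset_",
                                                         model$asset_names)]))
  expect_gte(cor(raw, counts), 0)
})

test_that("adding a positively-loaded asset never lowers the component score", {
  co <- varied_cohort(n = 200, seed = 13)
  model <- fit_asset_model(co)
  pos <- names(model$loadings)[model$loadings > 0]
  target <- pos[1]
  rows <- which(!as.data.frame(co)[[paste0("asset_", target)]])[1:20]
  rows <- rows[!is.na(rows)]
  before <- sesagree:::asset_component_score(model, co[rows, ])
  flipped <- co[rows, ]
  flipped[[paste0("asset_", target)]] <- TRUE
  after <- sesagree:::asset_component_score(model, flipped)
  expect_true(all(after >= before))
})

test_that("education uses guardian years below age 20, own years from 20", {
  scaler <- structure(list(range_min = 0, range_max = 18),
                      class = "education_scaler")
  r <- make_records(1, age = 17, education_years = 16,
                    guardian_education_years = 4)
  expect_equal(score_education(r, scaler), assign_interval_score(4, 0, 18))
  r$age <- 25
  expect_equal(score_education(r, scaler), assign_interval_score(16, 0, 18))
  expect_equal(score_education(make_records(1, age = 25, education_years = 11),
                               scaler), 5L)  # 11 in [10, 12)
  expect_equal(score_education(make_records(1, age = 30, education_years = 18),
                               scaler), 8L)
  expect_error(score_education(make_records(1, age = 17), scaler),
               "guardian", class = "wami_scoring_error")
})

test_that("income brackets sit at the 12.5% increment percentiles", {
  sample120 <- seq(50, 645, length.out = 120)
  br <- build_income_brackets(sample120)
  expect_equal(br$cutpoints_usd,
               unname(quantile(sample120, (1:8) * 0.125, type = 7)))
  expect_error(build_income_brackets(rep(100, 50)), "distinct",
               class = "wami_model_error")
})

test_that("income scoring matches the published bracket labels", {
  br <- study_income_brackets()
  expect_equal(score_income(make_records(1, income_usd_month = 99), br), 0L)
  expect_equal(score_income(make_records(1, income_usd_month = 500), br), 8L)
  # a value equal to a cutpoint falls in the higher bracket ($100-150 is 1)
  expect_equal(score_income(make_records(1, income_usd_month = 100), br), 1L)
  expect_equal(score_income(make_records(1, income_usd_month = 224), br), 4L)
  # reported bracket index overrides raw income
  expect_equal(score_income(make_records(1, income_usd_month = 99,
                                         income_bracket = 5), br), 5L)
  expect_error(score_income(make_records(1, income_usd_month = NA_real_), br),
               "income", class = "wami_scoring_error")
})

test_that("WAMI totals are bounded, additive and deterministic", {
  co <- varied_cohort(n = 300, seed = 21)
  w1 <- compute_wami(co)
  w2 <- compute_wami(co)
  expect_identical(w1$scores, w2$scores)
  s <- w1$scores
  for (comp in c("water_sanitation", "assets", "education", "income")) {
    expect_true(all(s[[comp]] >= 0L & s[[comp]] <= 8L), info = comp)
  }
  expect_true(all(s$total >= 0L & s$total <= 32L))
  expect_equal(s$total,
               s$water_sanitation + s$assets + s$education + s$income)
})

test_that("a best-on-everything record totals 32 and a worst one 0", {
  set.seed(31)
  recs <- make_records(50)
  z <- rnorm(50)
  for (col in paste0("asset_", wami_asset_names())) {
    recs[[col]] <- (z + rnorm(50)) > 0
    recs[[col]][1] <- TRUE
    recs[[col]][2] <- FALSE
  }
  recs$education_years <- round(runif(50, 0, 18))
  recs$education_years[1] <- 18
  recs$education_years[2] <- 0
  recs$water_improved[2] <- FALSE
  recs$sanitation_improved[2] <- FALSE
  recs$income_bracket <- sample(0:8, 50, replace = TRUE)
  recs$income_bracket[1] <- 8
  recs$income_bracket[2] <- 0
  w <- compute_wami(as_cohort(recs))
  expect_equal(w$scores$total[1], 32L)
  expect_equal(w$scores$total[2], 0L)
})

test_that("fitted scoring models serialize and reload bit-identically", {
  co <- varied_cohort(n = 120, seed = 17)
  w <- compute_wami(co)
  path <- tempfile(fileext = ".json")
  write_model(list(asset_model = w$asset_model,
                   education_scaler = w$education_scaler,
                   brackets = w$brackets), path)
  back <- read_model(path)
  # component scores at the exact range boundary may clamp by one ulp
  # after the decimal round-trip; the assigned scores must still agree
  expect_equal(suppressWarnings(score_assets(back$asset_model, co)),
               score_assets(w$asset_model, co))
  expect_equal(score_education(co, back$education_scaler),
               score_education(co, w$education_scaler))
  expect_equal(score_income(co, back$brackets), score_income(co, w$brackets))
})
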