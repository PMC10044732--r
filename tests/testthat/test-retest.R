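make_ba_cohort <- function(n = 300, seed = 41, p_reversal = 0.05) {
  cfg <- default_config(n = n, seed = seed)
  cfg$p_reversal <- p_reversal
  gen <- generate_cohort(cfg)
  co <- gen$cohort
  w <- compute_wami(co)
  ba <- sesagree:::ba_on_common_scale(co, w)
  list(cohort = co, wami = w, ba = ba, ids = attr(ba, "participant_ids"))
}

test_that("retest sample selection is seeded, bounded and well-typed", {
  s <- make_ba_cohort()
  n_out <- min(5L, s$ba$outlier_count)
  plan1 <- select_retest_sample(s$ba, s$cohort, s$ids, n_out, 10L, seed = 99)
  plan2 <- select_retest_sample(s$ba, s$cohort, s$ids, n_out, 10L, seed = 99)
  expect_identical(plan1, plan2)
  expect_length(plan1$outlier_ids, n_out)
  expect_length(plan1$control_ids, 10L)
  expect_length(intersect(plan1$outlier_ids, plan1$control_ids), 0L)
  flagged <- s$ids[s$ba$outlier_flags]
  expect_true(all(plan1$outlier_ids %in% flagged))
  expect_false(any(plan1$control_ids %in% flagged))

  empty <- select_retest_sample(s$ba, s$cohort, s$ids, 0L, 0L, seed = 1)
  expect_length(c(empty$outlier_ids, empty$control_ids), 0L)
  expect_error(
    select_retest_sample(s$ba, s$cohort, s$ids, s$ba$outlier_count + 1L, 0L,
                         seed = 1),
    "outliers", class = "retest_error")
})

test_that("substitution changes exactly the planned ladder values", {
  s <- make_ba_cohort(n = 200, seed = 43)
  co <- s$cohort
  # make planned retests verifiably different from the initial scores
  co$ladder_retest <- pmin(pmax(co$ladder + 2L, 1L), 10L)
  co$ladder_retest[co$ladder_retest == co$ladder] <-
    co$ladder[co$ladder_retest == co$ladder] - 2L
  plan <- structure(list(outlier_ids = co$participant_id[1:3],
                         control_ids = co$participant_id[10:12]),
                    class = "retest_plan")
  after <- substitute_retest(co, plan)
  changed <- which(after$ladder != co$ladder)
  expect_setequal(co$participant_id[changed],
                  c(plan$outlier_ids, plan$control_ids))
  for (col in setdiff(names(co), "ladder")) {
    expect_identical(after[[col]], co[[col]], info = col)
  }
  # idempotent and empty-plan identity
  expect_identical(substitute_retest(after, plan), after)
  empty <- structure(list(outlier_ids = character(), control_ids = character()),
                     class = "retest_plan")
  expect_identical(substitute_retest(co, empty), co)
  # single point update
  one <- structure(list(outlier_ids = co$participant_id[5],
                        control_ids = character()), class = "retest_plan")
  upd <- substitute_retest(co, one)
  expect_equal(upd$ladder[5], co$ladder_retest[5])

  co$ladder_retest[1] <- NA
  expect_error(substitute_retest(co, plan), "retest", class = "retest_error")
})

test_that("error-free scores make the before/after comparison a no-op", {
  cfg <- default_config(n = 300, seed = 47)
  cfg$p_reversal <- 0
  cfg$p_heaping <- 0
  co <- generate_cohort(cfg)$cohort
  co$ladder_retest <- co$ladder
  w <- compute_wami(co)
  ba <- sesagree:::ba_on_common_scale(co, w)
  plan <- select_retest_sample(ba, co, attr(ba, "participant_ids"),
                               min(5L, ba$outlier_count), 10L, seed = 7)
  cmp <- retest_comparison(co, w, plan, ks = c(10L, 3L))
  expect_true(all(cmp$delta$delta_rho == 0))
  expect_true(all(cmp$delta$delta_kappa == 0, na.rm = TRUE))
  expect_equal(cmp$outliers_before, cmp$outliers_after)
})

test_that("substituting error-free retests improves agreement under reversal", {
  # one representative replicate; the replicated direction check runs in
  # the acceptance suite
  cfg <- default_config(n = 595, seed = 53)
  gen <- generate_cohort(cfg)
  co <- gen$cohort
  w <- compute_wami(co)
  ba <- sesagree:::ba_on_common_scale(co, w)
  plan <- select_retest_sample(ba, co, attr(ba, "participant_ids"),
                               14L, 22L, seed = 11)
  expect_length(c(plan$outlier_ids, plan$control_ids), 36L)
  cmp <- retest_comparison(co, w, plan, ks = 10L)
  expect_gt(cmp$delta$delta_kappa[which(cmp$delta$k == 10)], 0)
  expect_lt(cmp$outliers_after, cmp$outliers_before)
})

test_that("frozen-threshold mode reuses the original outlier threshold", {
  s <- make_ba_cohort(n = 400, seed = 59)
  plan <- select_retest_sample(s$ba, s$cohort, s$ids,
                               min(5L, s$ba$outlier_count), 5L, seed = 3)
  frozen <- retest_comparison(s$cohort, s$wami, plan, ks = 10L,
                              freeze_threshold = TRUE)
  expect_equal(frozen$ba_after$outlier_threshold,
               frozen$ba_before$outlier_threshold)
})

test_that("a retest plan round-trips through its id/role text file", {
  plan <- structure(list(outlier_ids = c("P01", "P02"),
                         control_ids = c("P10", "P11", "P12")),
                    class = "retest_plan")
  path <- temp_tsv()
  write_retest_plan(plan, path)
  back <- read_retest_plan(path)
  expect_identical(back$outlier_ids, plan$outlier_ids)
  expect_identical(back$control_ids, plan$control_ids)
  writeLines("garbage", path)
  expect_error(read_retest_plan(path), class = "retest_error")
})
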