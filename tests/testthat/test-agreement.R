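test_that("spearman_rho handles exact, tied and degenerate inputs", {
  expect_equal(spearman_rho(1:10, (1:10)^3), 1)
  expect_equal(spearman_rho(1:10, 11 - (1:10)), -1)
  # mid-ranks: x -> (1, 2.5, 2.5, 4), y -> (1, 3, 2, 4)
  expect_equal(spearman_rho(c(1, 2, 2, 4), c(1, 3, 2, 4)),
               spearman_oracle(c(1, 2, 2, 4), c(1, 3, 2, 4)))
  expect_equal(spearman_rho(c(1, 2, 2, 4), c(1, 3, 2, 4)), 0.9486833,
               tolerance = 1e-7)
  expect_error(spearman_rho(rep(3, 5), 1:5), "constant",
               class = "agreement_error")
  expect_error(spearman_rho(1:4, 1:5), "length", class = "agreement_error")
  expect_error(spearman_rho(c(1, NA, 3), c(1, 2, 3)),
               class = "agreement_error")
})

test_that("spearman_rho is invariant under strictly monotone transforms", {
  set.seed(11)
  x <- sample(1:10, 200, replace = TRUE)
  y <- sample(1:10, 200, replace = TRUE)
  base <- spearman_rho(x, y)
  expect_equal(spearman_rho(exp(x), y), base)
  expect_equal(spearman_rho(x, qlogis((y + 0.5) / 11)), base)
})

test_that("weighted kappa matches hand-derived values", {
  x <- sample(1:5, 100, replace = TRUE)
  expect_equal(weighted_kappa(x, x), 1)
  # 2x2 observed table ((45,15),(25,15))/100: po=0.60, pe=0.54 -> 0.1304
  x2 <- rep(c(1, 1, 2, 2), times = c(45, 15, 25, 15))
  y2 <- rep(c(1, 2, 1, 2), times = c(45, 15, 25, 15))
  expect_equal(weighted_kappa(x2, y2, categories = 1:2), 0.06 / 0.46,
               tolerance = 1e-12)
  expect_message(
    expect_equal(weighted_kappa(rep(2, 10), rep(2, 10), categories = 1:5), 1),
    "convention")
})

test_that("weighted kappa equals the cell-loop oracle on random tables", {
  set.seed(12)
  for (rep in 1:40) {
    k <- sample(2:5, 1)
    n <- sample(10:50, 1)
    x <- sample(1:k, n, replace = TRUE)
    y <- sample(1:k, n, replace = TRUE)
    if (sd(x) == 0 && sd(y) == 0) next
    expect_equal(weighted_kappa(x, y, categories = 1:k),
                 kappa_oracle(x, y, 1:k), tolerance = 1e-12)
  }
})

test_that("weighted kappa is symmetric and spacing-invariant", {
  set.seed(13)
  x <- sample(1:5, 300, replace = TRUE)
  y <- pmin(pmax(x + sample(-1:1, 300, replace = TRUE), 1), 5)
  expect_equal(weighted_kappa(x, y, 1:5), weighted_kappa(y, x, 1:5))
  # common relabeling preserving order and spacing (positions in universe)
  relab <- c(10, 20, 30, 40, 50)
  expect_equal(weighted_kappa(relab[x], relab[y], categories = relab),
               weighted_kappa(x, y, categories = 1:5))
  expect_error(weighted_kappa(x, c(y[-1], 7), categories = 1:5),
               "universe", class = "agreement_error")
})

test_that("Landis-Koch labels follow the published cutpoints", {
  expect_equal(interpret_kappa(0.26), "fair")
  expect_equal(interpret_kappa(0.85), "almost perfect")
  expect_equal(interpret_kappa(-0.5), "poor")
  expect_equal(interpret_kappa(0.20), "poor")       # boundary to lower label
  expect_equal(interpret_kappa(0.405), "moderate")  # printed gap (0.40,0.41)
  expect_equal(interpret_kappa(c(0.40, 0.61, 1)),
               c("fair", "substantial", "almost perfect"))
  expect_error(interpret_kappa(1.2), class = "agreement_error")
})

test_that("Bland-Altman flags match the documented percentile estimator", {
  x <- rep(5, 100)
  expect_equal(bland_altman(x, x)$outlier_count, 0L)
  # d = 1..100: type-7 95th percentile of |d| is 95.05, so 5 are flagged
  y <- rep(0, 100)
  ba <- bland_altman(1:100, y, percentile = 95, mode = "absolute")
  expect_equal(ba$outlier_count, 5L)
  expect_equal(ba$outlier_threshold, 95.05)
  expect_equal(ba$diff, 1:100)
  expect_equal(ba$mean, (1:100) / 2)
  ba2 <- bland_altman(1:100, y, mode = "two_sided")
  expect_equal(ba2$outlier_count,
               sum(1:100 < ba2$outlier_threshold[1] |
                     1:100 > ba2$outlier_threshold[2]))
  expect_error(bland_altman(1:10, 1:10, k_x = 10, k_y = 5),
               "same number of categories", class = "agreement_error")
})

test_that("agreement_suite mirrors the published table layout", {
  co <- generate_cohort(default_config(n = 595, seed = 31))$cohort
  w <- compute_wami(co)
  tab <- agreement_suite(co, w)
  expect_equal(tab$scale, c("32-point", "10-point", "5-categories",
                            "4-categories", "3-categories"))
  expect_true(is.na(tab$kappa[1]))  # no kappa for the raw 32-vs-10 pairing
  expect_true(all(!is.na(tab$kappa[-1])))
  expect_true(all(abs(tab$rho) <= 1) && all(abs(tab$kappa[-1]) <= 1))
  expect_equal(tab$kappa_label[-1], interpret_kappa(tab$kappa[-1]))
  # the 10-category version preserves the raw rank correlation closely;
  # coarser scales attenuate it somewhat through ties
  expect_lt(abs(tab$rho[1] - tab$rho[2]), 0.04)
  expect_true(all(abs(tab$rho - tab$rho[1]) < 0.08))
})

test_that("a ladder perfectly concordant with WAMI gives perfect agreement", {
  co <- generate_cohort(default_config(n = 400, seed = 37))$cohort
  w <- compute_wami(co)
  idx <- match(w$scores$participant_id, co$participant_id)
  co$ladder[idx] <- rescale_wami_to_10(w$scores$total)$categories
  tab <- agreement_suite(co, w, ks = 10L)
  expect_equal(tab$rho[tab$scale == "10-point"], 1)
  expect_equal(tab$kappa[tab$scale == "10-point"], 1)
  expect_equal(tab$rho[tab$scale == "32-point"], 1, tolerance = 0.05)
})

test_that("the Bland-Altman plot renders without touching the caller's RNG", {
  ba <- bland_altman(sample(1:10, 80, replace = TRUE),
                     sample(1:10, 80, replace = TRUE))
  set.seed(123)
  before <- .Random.seed
  png(tempfile(fileext = ".png"))
  plot(ba)
  dev.off()
  expect_identical(.Random.seed, before)
})
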