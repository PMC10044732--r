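#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties receive average ranks).
#' Complete-case handling is the caller's responsibility; missing values
#' are an error, as is zero variance in either vector.
#'
#' @param x,y Numeric or ordinal vectors of equal length (at least 2).
#' @return Correlation in \[-1, 1\].
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) {
    stop_ses("x and y must have equal length", class = "agreement_error")
  }
  if (length(x) < 2L) {
    stop_ses("need at least 2 pairs", class = "agreement_error")
  }
  if (anyNA(x) || anyNA(y)) {
    stop_ses("missing values; pass complete cases", class = "agreement_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_ses("rank correlation undefined for a constant vector",
             class = "agreement_error")
  }
  unname(stats::cor(x, y, method = "spearman"))
}

#' Fleiss-Cohen (quadratic-weighted) kappa
#'
#' Chance-corrected agreement between two ordinal ratings with
#' disagreement weights growing as the squared distance between category
#' positions: kappa = 1 - sum(w * O) / sum(w * E), where w[i,j] =
#' (i - j)^2, O is the observed joint proportion matrix over the declared
#' category universe and E the product of its marginals. Categories absent
#' from the data but present in the universe are legal (empty rows and
#' columns). When both vectors are constant and identical the statistic's
#' denominator is zero; 1 is returned by convention with a message.
#'
#' @param x,y Category vectors of equal length, drawn from `categories`.
#' @param categories Ordered category universe shared by both scales
#'   (default: sorted union of the observed values).
#' @param weighting Only `"quadratic"` (Fleiss-Cohen) is offered as a
#'   default; `"linear"` is available as an escape hatch.
#' @return Kappa in \[-1, 1\].
#' @export
weighted_kappa <- function(x, y, categories = NULL,
                           weighting = c("quadratic", "linear")) {
  weighting <- match.arg(weighting)
  if (length(x) != length(y)) {
    stop_ses("x and y must have equal length", class = "agreement_error")
  }
  if (anyNA(x) || anyNA(y)) {
    stop_ses("missing values; pass complete cases", class = "agreement_error")
  }
  if (is.null(categories)) categories <- sort(unique(c(x, y)))
  if (!all(x %in% categories) || !all(y %in% categories)) {
    stop_ses("values outside the declared category universe",
             class = "agreement_error")
  }
  k <- length(categories)
  O <- table(factor(x, levels = categories),
             factor(y, levels = categories)) / length(x)
  E <- outer(rowSums(O), colSums(O))
  pos <- seq_len(k)
  w <- if (weighting == "quadratic") {
    outer(pos, pos, function(i, j) (i - j)^2)
  } else {
    outer(pos, pos, function(i, j) abs(i - j))
  }
  den <- sum(w * E)
  if (den == 0) {
    num <- sum(w * O)
    if (num == 0) {
      message("both ratings constant and equal; kappa = 1 by convention")
      return(1)
    }
    stop_ses("kappa undefined: zero expected disagreement with nonzero ",
             "observed disagreement", class = "agreement_error")
  }
  1 - sum(w * O) / den
}

#' Landis-Koch interpretation of a kappa value
#'
#' Verbal agreement labels: poor (-1 to 0.20), fair (0.20 to 0.40),
#' moderate (0.41 to 0.60), substantial (0.61 to 0.80), almost perfect
#' (0.81 to 1.00). Boundaries belong to the lower label (0.20 is "poor"),
#' and the printed gaps such as (0.40, 0.41) are assigned to the upper
#' label so the map is total.
#'
#' @param kappa Numeric in \[-1, 1\] (vectorized).
#' @return Character labels.
#' @export
interpret_kappa <- function(kappa) {
  if (any(is.na(kappa)) || any(kappa < -1 | kappa > 1)) {
    stop_ses("kappa must lie in [-1, 1]", class = "agreement_error")
  }
  labels <- c("poor", "fair", "moderate", "substantial", "almost perfect")
  labels[findInterval(kappa, c(0.20, 0.40, 0.60, 0.80), left.open = TRUE) + 1L]
}

#' Bland-Altman percentile outlier analysis
#'
#' Computes per-participant differences d = x - y and means (x + y)/2 for
#' two scores on a common scale and flags discordant participants. With
#' `mode = "absolute"` (default) a participant is an outlier when |d|
#' exceeds the `percentile`-th empirical percentile of |d| (strictly);
#' with `mode = "two_sided"` when d falls outside the central
#' `percentile`% band. Percentiles use linear interpolation between order
#' statistics (R quantile type 7) — outlier counts on integer-valued
#' differences are sensitive to this convention, so it is fixed.
#'
#' @param x,y Numeric vectors on the same scale (same category count).
#' @param percentile Percentile (default 95).
#' @param mode `"absolute"` or `"two_sided"`.
#' @param k_x,k_y Optional declared category counts for the two scales;
#'   when both given they must match.
#' @return An object of class `bland_altman`: `mean`, `diff`,
#'   `outlier_threshold` (one value, or the two band edges for
#'   `two_sided`), `outlier_flags`, `outlier_count`, `outlier_fraction`,
#'   `percentile`, `mode`, `n`.
#' @export
bland_altman <- function(x, y, percentile = 95,
                         mode = c("absolute", "two_sided"),
                         k_x = NULL, k_y = NULL) {
  mode <- match.arg(mode)
  if (length(x) != length(y)) {
    stop_ses("x and y must have equal length", class = "agreement_error")
  }
  if (!is.null(k_x) && !is.null(k_y) && k_x != k_y) {
    stop_ses("Bland-Altman requires both scores on the same number of ",
             "categories (", k_x, " vs ", k_y, ")", class = "agreement_error")
  }
  if (anyNA(x) || anyNA(y)) {
    stop_ses("missing values; pass complete cases", class = "agreement_error")
  }
  d <- x - y
  m <- (x + y) / 2
  if (mode == "absolute") {
    thr <- unname(stats::quantile(abs(d), percentile / 100, type = 7))
    flags <- abs(d) > thr
  } else {
    alpha <- (1 - percentile / 100) / 2
    thr <- unname(stats::quantile(d, c(alpha, 1 - alpha), type = 7))
    flags <- d < thr[1L] | d > thr[2L]
  }
  structure(list(mean = m, diff = d, outlier_threshold = thr,
                 outlier_flags = flags, outlier_count = sum(flags),
                 outlier_fraction = mean(flags), percentile = percentile,
                 mode = mode, n = length(d)),
            class = "bland_altman")
}

#' Diagnostic Bland-Altman plot
#'
#' Scatter of per-participant differences against means, with jitter (the
#' scores are integers), the zero line, and the outlier threshold(s);
#' flagged participants are drawn filled.
#'
#' @param x A [bland_altman] result.
#' @param jitter_amount Jitter applied to both axes for legibility.
#' @param ... Passed to [plot()].
#' @return Invisibly, `x`.
#' @export
plot.bland_altman <- function(x, jitter_amount = 0.15, ...) {
  # cosmetic jitter only; seeded (without disturbing the caller's RNG
  # state) so the figure is reproducible
  xy <- with_seed(1L, list(m = jitter(x$mean, amount = jitter_amount),
                           d = jitter(x$diff, amount = jitter_amount)))
  graphics::plot(xy$m, xy$d,
                 pch = ifelse(x$outlier_flags, 19, 1),
                 col = ifelse(x$outlier_flags, "firebrick", "grey30"),
                 xlab = "mean of paired scores",
                 ylab = "difference (objective - subjective)", ...)
  graphics::abline(h = 0, col = "grey70")
  thr <- if (x$mode == "absolute") c(-1, 1) * x$outlier_threshold else
    x$outlier_threshold
  graphics::abline(h = thr, col = "firebrick", lty = 2)
  invisible(x)
}

#' @export
print.bland_altman <- function(x, ...) {
  cat("<bland_altman> n = ", x$n, ", ", x$outlier_count, " outliers (",
      sprintf("%.1f%%", 100 * x$outlier_fraction), ") beyond the ",
      x$percentile, "th percentile (", x$mode, ")\n", sep = "")
  invisible(x)
}

#' Agreement between WAMI and ladder across category scales
#'
#' Reproduces the layout of the headline agreement table: the raw 32-point
#' WAMI against the 10-point ladder (Spearman only — quadratic kappa
#' requires a shared category universe), then both scores rescaled to
#' common 10/5/4/3-category scales with Spearman rho, Fleiss-Cohen kappa
#' and its Landis-Koch label per scale. Complete cases (scorable WAMI and
#' observed ladder) only.
#'
#' @param cohort A [ses_cohort][as_cohort].
#' @param wami A [wami_result][compute_wami] for the cohort (computed when
#'   `NULL`).
#' @param ks Category counts to compare on (default 10, 5, 4, 3).
#' @return A data frame with columns `scale`, `k`, `n`, `rho`, `kappa`,
#'   `kappa_label`; attribute `"schemes"` holds the fitted
#'   [rescale_scheme][build_rescale_scheme]s per measure and k.
#' @export
agreement_suite <- function(cohort, wami = NULL, ks = c(10L, 5L, 4L, 3L)) {
  stopifnot(inherits(cohort, "ses_cohort"))
  if (is.null(wami)) wami <- compute_wami(cohort)
  pairs <- agreement_pairs(cohort, wami)
  if (nrow(pairs) < 2L) {
    stop_ses("fewer than 2 complete WAMI/ladder pairs",
             class = "agreement_error")
  }
  rows <- list(data.frame(scale = "32-point", k = NA_integer_,
                          n = nrow(pairs),
                          rho = spearman_rho(pairs$wami, pairs$ladder),
                          kappa = NA_real_, kappa_label = NA_character_))
  schemes <- list()
  for (k in ks) {
    ww <- build_rescale_scheme(pairs$wami, k, source_label = "wami_total")
    wami_k <- apply_rescale(pairs$wami, ww)
    if (k == 10L) {
      # the ladder is already a 10-category scale
      ladder_k <- pairs$ladder
      schemes[[paste0("k", k)]] <- list(wami = ww, ladder = NULL)
    } else {
      ll <- build_rescale_scheme(pairs$ladder, k, source_label = "ladder")
      ladder_k <- apply_rescale(pairs$ladder, ll)
      schemes[[paste0("k", k)]] <- list(wami = ww, ladder = ll)
    }
    kap <- weighted_kappa(wami_k, ladder_k, categories = seq_len(k))
    rows[[length(rows) + 1L]] <- data.frame(
      scale = if (k == 10L) "10-point" else paste0(k, "-categories"),
      k = as.integer(k), n = nrow(pairs),
      rho = spearman_rho(wami_k, ladder_k),
      kappa = kap, kappa_label = interpret_kappa(kap))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "schemes") <- schemes
  out
}

# complete-case WAMI-total / ladder pairs for a cohort
agreement_pairs <- function(cohort, wami) {
  idx <- match(wami$scores$participant_id, cohort$participant_id)
  ladder <- cohort$ladder[idx]
  keep <- !is.na(ladder)
  data.frame(participant_id = wami$scores$participant_id[keep],
             wami = wami$scores$total[keep], ladder = ladder[keep])
}
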