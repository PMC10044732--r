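#' Build an ordinal rescaling scheme
#'
#' Maps a score scale (e.g. the 0-32 WAMI or 1-10 ladder) onto `k` ordered
#' categories. With `method = "quantile"` the k-1 cutpoints are placed at
#' the i/k empirical quantiles of the supplied scores and snapped to the
#' nearest integer boundary, so category masses stay as equal as the
#' discrete score distribution allows. With `method = "user_cutpoints"`
#' explicit thresholds are validated and stored, which lets published
#' conventional cutoffs be replicated exactly.
#'
#' @param scores Numeric scores from the source scale (used for quantiles
#'   and to record the source range).
#' @param k Target category count, one of 3, 4, 5, 10.
#' @param method `"quantile"` or `"user_cutpoints"`.
#' @param cutpoints Required for `method = "user_cutpoints"`: k-1
#'   non-decreasing thresholds.
#' @param source_label Label describing the source scale.
#' @return An object of class `rescale_scheme`: `source_label`,
#'   `source_min`, `source_max`, `k`, `cutpoints`, `method`,
#'   `category_labels`.
#' @export
build_rescale_scheme <- function(scores, k,
                                 method = c("quantile", "user_cutpoints"),
                                 cutpoints = NULL, source_label = "score") {
  method <- match.arg(method)
  if (!k %in% c(3L, 4L, 5L, 10L)) {
    stop_ses("k must be one of 3, 4, 5, 10", class = "rescale_error")
  }
  scores <- scores[!is.na(scores)]
  if (length(scores) < 2L) {
    stop_ses("need at least 2 scores", class = "rescale_error")
  }
  if (method == "quantile") {
    if (length(unique(scores)) < k) {
      stop_ses("need at least ", k, " distinct score values for quantile ",
               "cutpoints", class = "rescale_error")
    }
    # snap each i/k quantile to the achievable score boundary that best
    # balances category masses; a cutpoint c splits {s < c} from {s >= c},
    # so the rule depends on ranks only and survives monotone transforms
    u <- sort(unique(scores))
    n_below <- vapply(u, function(c) sum(scores < c), numeric(1))
    targets <- seq_len(k - 1L) * length(scores) / k
    cutpoints <- vapply(targets, function(t) u[which.min(abs(n_below - t))],
                        numeric(1))
    cutpoints <- cummax(cutpoints)
  } else {
    if (is.null(cutpoints) || length(cutpoints) != k - 1L) {
      stop_ses("user_cutpoints requires k-1 thresholds",
               class = "rescale_error")
    }
    if (is.unsorted(cutpoints)) {
      stop_ses("cutpoints must be non-decreasing", class = "rescale_error")
    }
  }
  structure(list(
    source_label = source_label,
    source_min = min(scores),
    source_max = max(scores),
    k = as.integer(k),
    cutpoints = as.numeric(cutpoints),
    method = method,
    category_labels = seq_len(k)
  ), class = "rescale_scheme")
}

#' @export
print.rescale_scheme <- function(x, ...) {
  cat("<rescale_scheme> ", x$source_label, " [", x$source_min, ", ",
      x$source_max, "] -> ", x$k, " categories; cutpoints ",
      paste(x$cutpoints, collapse = ", "), " (", x$method, ")\n", sep = "")
  invisible(x)
}

#' Apply a rescaling scheme
#'
#' Assigns each score to a category 1..k via left-closed/right-open
#' cutpoint intervals (top category closed). Scores outside the recorded
#' source range are clamped with a warning.
#'
#' @param score Numeric vector.
#' @param scheme A [rescale_scheme][build_rescale_scheme].
#' @return Integer vector of categories in 1..k.
#' @export
apply_rescale <- function(score, scheme) {
  stopifnot(inherits(scheme, "rescale_scheme"))
  if (any(score < scheme$source_min | score > scheme$source_max,
          na.rm = TRUE)) {
    warning("scores outside the source range clamped")
    score <- pmin(pmax(score, scheme$source_min), scheme$source_max)
  }
  as.integer(findInterval(score, scheme$cutpoints, left.open = FALSE) + 1L)
}

#' Rescale WAMI totals to a 10-point ordinal scale
#'
#' Builds the 10-category quantile scheme from the WAMI totals' own
#' distribution (so the ordinal version matches the original distribution)
#' and applies it, making the WAMI directly comparable with the 10-rung
#' ladder.
#'
#' @param scores Numeric WAMI totals.
#' @return A list with `scheme`, `categories` (1..10 per score), and
#'   `median` of the rescaled categories.
#' @export
rescale_wami_to_10 <- function(scores) {
  scheme <- build_rescale_scheme(scores, 10L, "quantile",
                                 source_label = "wami_total")
  categories <- apply_rescale(scores, scheme)
  list(scheme = scheme, categories = categories,
       median = stats::median(categories))
}
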