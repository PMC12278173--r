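#' Mean daily score
#'
#' @param totals Numeric vector of daily total scores (at least one).
#' @return The arithmetic mean.
#' @export
mean_score <- function(totals) {
  if (length(totals) == 0) {
    stop("cannot average an empty score series", call. = FALSE)
  }
  mean(totals)
}

#' Adherence trend over time
#'
#' Ordinary least-squares slope of the daily total on the day index, in score
#' units per day. A positive slope means improving adherence. With fewer than
#' two observations, or no variation in the day index, the slope is undefined
#' and `NA_real_` is returned with a warning.
#'
#' @param day Numeric day indices.
#' @param total Daily total scores, same length as `day`.
#' @return The OLS slope, or `NA_real_` when undefined.
#' @export
#' @examples
#' adherence_trend(0:2, c(10, 20, 30))  # 10
adherence_trend <- function(day, total) {
  stopifnot(length(day) == length(total))
  if (length(day) < 2 || length(unique(day)) < 2) {
    warning("adherence trend undefined with fewer than two distinct days",
            call. = FALSE)
    return(NA_real_)
  }
  unname(coef(lm(total ~ day))[["day"]])
}

#' Classify a cumulative score into an adherence band
#'
#' Bins the per-period mean score into labelled half-open intervals
#' `[0, c1), [c1, c2), ..., [ck, max]`; the top bin is closed at the maximum.
#' The defaults split the 0–30 range into thirds: low `[0, 10)`, moderate
#' `[10, 20)`, high `[20, 30]` — the framework names cumulative
#' classification but fixes no thresholds, so these are transparent,
#' overridable defaults.
#'
#' @param mean_total Mean (or cumulative, if you pass your own cutpoints on
#'   that scale) score; vectorised.
#' @param cutpoints Strictly increasing thresholds within
#'   `(0, max_possible)`.
#' @param labels One label per bin: `length(cutpoints) + 1`.
#' @param max_possible Upper end of the score scale (default 30).
#' @return Character vector of class labels.
#' @export
#' @examples
#' classify_cumulative(c(0, 10, 30))  # "low" "moderate" "high"
classify_cumulative <- function(mean_total, cutpoints = c(10, 20),
                                labels = c("low", "moderate", "high"),
                                max_possible = 30) {
  if (length(cutpoints) == 0 || any(diff(cutpoints) <= 0)) {
    stop("cutpoints must be strictly increasing", call. = FALSE)
  }
  if (any(cutpoints <= 0) || any(cutpoints >= max_possible)) {
    stop("cutpoints must lie strictly inside (0, ", max_possible, ")",
         call. = FALSE)
  }
  if (length(labels) != length(cutpoints) + 1) {
    stop("need exactly ", length(cutpoints) + 1, " labels for ",
         length(cutpoints), " cutpoints", call. = FALSE)
  }
  if (any(mean_total < 0 | mean_total > max_possible, na.rm = TRUE)) {
    stop("mean scores must lie in [0, ", max_possible, "]", call. = FALSE)
  }
  labels[findInterval(mean_total, cutpoints) + 1]
}

#' Per-subject longitudinal adherence summary
#'
#' Aggregates a table of daily totals into one row per subject: number of
#' observed days, mean score, OLS adherence trend (in score units per day;
#' `NA` for single-day subjects) and the adherence class from
#' [classify_cumulative()].
#'
#' @param scores_summary Data frame with columns `subject_id`, `day`, `total`
#'   — the `summary` element of an `nl_score_set`, or a CSV read back with
#'   [read_scores()].
#' @param cutpoints,labels,max_possible Passed to [classify_cumulative()].
#' @param use Classify on the per-day `"mean"` (default; invariant to the
#'   length of the observation period) or on the raw `"sum"` of daily totals
#'   (cutpoints must then be chosen on the cumulative scale).
#' @return A tibble with columns `subject_id`, `n_days`, `mean_score`,
#'   `trend_slope`, `class_label`.
#' @export
summarize_adherence <- function(scores_summary, cutpoints = c(10, 20),
                                labels = c("low", "moderate", "high"),
                                max_possible = 30,
                                use = c("mean", "sum")) {
  use <- match.arg(use)
  scores_summary <- tibble::as_tibble(scores_summary)
  for (col in c("subject_id", "day", "total")) {
    if (!col %in% names(scores_summary)) {
      stop("scores_summary is missing column '", col, "'", call. = FALSE)
    }
  }
  scores_summary <- dplyr::arrange(scores_summary, .data$subject_id,
                                   .data$day)
  out <- dplyr::summarise(
    dplyr::group_by(scores_summary, .data$subject_id),
    n_days = dplyr::n(),
    mean_score = mean_score(.data$total),
    cumulative = sum(.data$total),
    trend_slope = suppressWarnings(adherence_trend(.data$day, .data$total)),
    .groups = "drop"
  )
  basis <- if (use == "mean") out$mean_score else out$cumulative
  out$class_label <- classify_cumulative(basis, cutpoints = cutpoints,
                                         labels = labels,
                                         max_possible = if (use == "mean")
                                           max_possible else Inf)
  out[, c("subject_id", "n_days", "mean_score", "trend_slope", "class_label")]
}
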