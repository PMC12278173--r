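#' Traffic-light piecewise scoring rules
#'
#' The NutriLight engine awards each food group 0, 1 or 2 points by comparing
#' the observed daily intake `x` (g/day) to the recommended amount `r`
#' (g/day). The shape of the rule depends on the traffic-light category:
#'
#' * **Green** (encouraged): 2 points when the recommendation is met
#'   (`x >= r`), 1 point for partial intake (`0 < x < r`), 0 points if absent
#'   (`x = 0`). Intake above the recommendation keeps the full 2 points — the
#'   rule is monotone non-decreasing and capped.
#' * **Yellow** (moderation): 2 points for meeting the recommendation, i.e.
#'   `x` within the band `[(1 - tolerance) * r, (1 + tolerance) * r]`; 1 point
#'   for a mild deviation on either side (`0 < x` below the band, or above it
#'   but below `2r`); 0 points if under-consumed (`x = 0`) or over-consumed
#'   (`x >= 2r`). With `tolerance = 0` (the default) the 2-point band
#'   collapses to `x = r` exactly.
#' * **Red** (limited): 2 points for staying within the limit (`x <= r`,
#'   including zero intake), 1 point for slightly exceeding it
#'   (`r < x < 2r`), 0 points for excess (`x >= 2r`). In the limiting case
#'   `r = 0` the 1-point band is empty: 2 points iff `x = 0`, else 0.
#'
#' Boundary points always belong to the band whose verbal description covers
#' them: `x = r` is "meeting" (green, yellow) or "within the limit" (red), and
#' `x = 2r` falls in the 0-point band for yellow and red. All comparisons use
#' a relative tolerance of 1e-9 so that boundaries behave identically for
#' exact and computed inputs. All three functions are vectorised over `x` and
#' `r` and scale-invariant: `score(k * x, k * r) = score(x, r)` for `k > 0`.
#'
#' @param x Observed intake in g/day (non-negative; vectorised).
#' @param r Recommended amount in g/day (positive for green and yellow;
#'   non-negative for red).
#' @param tolerance Relative half-width of the yellow 2-point band, in
#'   `[0, 0.5)`.
#'
#' @return Integer points in `{0, 1, 2}`, same length as `x`.
#' @name scoring-rules
#' @examples
#' score_green(c(0, 150, 300, 450), r = 300)  # 0 1 2 2
#' score_yellow(c(0, 125, 250, 375, 500), r = 250)  # 0 1 2 1 0
#' score_red(c(0, 7, 14, 21, 28), r = 14)  # 2 2 2 1 0
NULL

#' @rdname scoring-rules
#' @export
score_green <- function(x, r) {
  .check_xr(x, r, positive_r = TRUE)
  n <- max(length(x), length(r))
  x <- rep_len(x, n)
  r <- rep_len(r, n)
  ifelse(.nl_ge(x, r), 2L, ifelse(x > 0, 1L, 0L))
}

#' @rdname scoring-rules
#' @export
score_yellow <- function(x, r, tolerance = 0) {
  .check_xr(x, r, positive_r = TRUE)
  if (length(tolerance) != 1L || is.na(tolerance) ||
      tolerance < 0 || tolerance >= 0.5) {
    stop("tolerance must be a single value in [0, 0.5)", call. = FALSE)
  }
  n <- max(length(x), length(r))
  x <- rep_len(x, n)
  r <- rep_len(r, n)
  in_band <- .nl_ge(x, (1 - tolerance) * r) & .nl_le(x, (1 + tolerance) * r)
  ifelse(in_band, 2L,
         ifelse(x == 0 | .nl_ge(x, 2 * r), 0L, 1L))
}

#' @rdname scoring-rules
#' @export
score_red <- function(x, r) {
  .check_xr(x, r, positive_r = FALSE)
  n <- max(length(x), length(r))
  x <- rep_len(x, n)
  r <- rep_len(r, n)
  ifelse(r == 0,
         ifelse(x == 0, 2L, 0L),
         ifelse(.nl_le(x, r), 2L,
                ifelse(.nl_ge(x, 2 * r), 0L, 1L)))
}

.check_xr <- function(x, r, positive_r) {
  if (any(is.na(x)) || any(x < 0)) {
    stop("intake x must be non-negative and non-missing", call. = FALSE)
  }
  if (positive_r) {
    if (any(is.na(r)) || any(r <= 0)) {
      stop("recommended amount r must be > 0 for this category", call. = FALSE)
    }
  } else if (any(is.na(r)) || any(r < 0)) {
    stop("recommended amount r must be >= 0", call. = FALSE)
  }
  invisible(TRUE)
}

# dispatch on category; vectorised over x, r, category
.score_points <- function(x, r, category, tolerance) {
  points <- integer(length(x))
  for (cat in unique(category)) {
    idx <- which(category == cat)
    points[idx] <- switch(
      cat,
      green = score_green(x[idx], r[idx]),
      yellow = score_yellow(x[idx], r[idx], tolerance = tolerance),
      red = score_red(x[idx], r[idx]),
      stop("unknown category '", cat, "'", call. = FALSE)
    )
  }
  points
}

#' Score one food group's intake
#'
#' Dispatches on the group's traffic-light category to the matching piecewise
#' rule and returns the scored record, including the intake/recommendation
#' ratio.
#'
#' @param intake_g Observed intake in g/day.
#' @param spec A one-row food-group table as returned by [food_group()] (or a
#'   row of `config$groups`).
#' @param config An `nl_config`; supplies the yellow tolerance.
#' @return A one-row tibble with columns `food_group`, `category`, `intake_g`,
#'   `reference_g`, `ratio` (`NA` when `R = 0`) and `points`.
#' @export
#' @examples
#' score_group(300, food_group("vegetables", "green", 300))
score_group <- function(intake_g, spec, config = NULL) {
  spec <- tibble::as_tibble(spec)
  stopifnot(nrow(spec) == 1L)
  tolerance <- if (is.null(config)) 0 else config$yellow_tolerance
  r <- spec$recommended_intake_g
  tibble::tibble(
    food_group = spec$name,
    category = spec$category,
    intake_g = as.numeric(intake_g),
    reference_g = r,
    ratio = if (r > 0) intake_g / r else NA_real_,
    points = .score_points(intake_g, r, spec$category, tolerance)
  )
}

#' Bundle one subject-day of intakes
#'
#' @param subject_id Subject identifier.
#' @param day Day index (non-negative integer) or date.
#' @param amounts Named numeric vector of g/day amounts, names matching the
#'   configured food groups.
#' @return An object of class `nl_daily_intake`.
#' @export
daily_intake <- function(subject_id, day, amounts) {
  if (is.null(names(amounts)) || any(names(amounts) == "")) {
    stop("amounts must be a fully named numeric vector", call. = FALSE)
  }
  if (any(is.na(amounts)) || any(amounts < 0)) {
    stop("all amounts must be non-negative and non-missing", call. = FALSE)
  }
  structure(
    list(subject_id = as.character(subject_id), day = day,
         amounts = amounts),
    class = "nl_daily_intake"
  )
}

#' Score one subject-day against a configuration
#'
#' Applies the per-category piecewise rule to every configured group and sums
#' the points into a daily total with green/yellow/red subscores. How food
#' groups absent from the record are handled is an explicit policy:
#'
#' * `"strict"` (default): any configured group missing from the record is an
#'   error naming the group. Silent imputation corrupts totals.
#' * `"impute_zero"`: missing groups are scored at `x = 0` and a warning lists
#'   them.
#' * `"rescale"`: only the groups present are scored; the result additionally
#'   carries `total_rescaled`, the total renormalised to the full
#'   configuration's 0–30 scale
#'   (`total * max_possible_score(config) / (2 * n_scored)`).
#'
#' Amounts for groups not present in the configuration are always an error.
#'
#' @param intake An [daily_intake()] object, or a bare named numeric vector of
#'   g/day amounts.
#' @param config An `nl_config` (default [default_config()]).
#' @param missing_policy One of `"strict"`, `"impute_zero"`, `"rescale"`.
#' @return An object of class `nl_daily_score`: a list with `subject_id`,
#'   `day`, `group_scores` (tibble, one row per scored group), `total`,
#'   `green_subscore`, `yellow_subscore`, `red_subscore`, `max_possible`, and
#'   `total_rescaled` (`NA` unless `missing_policy = "rescale"`).
#' @export
#' @examples
#' cfg <- default_config()
#' ideal <- with(cfg$groups, stats::setNames(
#'   ifelse(category == "red", recommended_intake_g / 2, recommended_intake_g),
#'   name))
#' score_day(ideal, cfg)$total  # 30
score_day <- function(intake, config = default_config(),
                      missing_policy = c("strict", "impute_zero", "rescale")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(config, "nl_config"))
  if (inherits(intake, "nl_daily_intake")) {
    subject_id <- intake$subject_id
    day <- intake$day
    amounts <- intake$amounts
  } else {
    subject_id <- NA_character_
    day <- NA_integer_
    amounts <- intake
  }
  if (is.null(names(amounts))) {
    stop("intake amounts must be named by food group", call. = FALSE)
  }
  if (any(is.na(amounts)) || any(amounts < 0)) {
    stop("all intake amounts must be non-negative and non-missing",
         call. = FALSE)
  }
  groups <- config$groups
  unknown <- setdiff(names(amounts), groups$name)
  if (length(unknown) > 0) {
    stop("intake contains group(s) not in the configuration: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(groups$name, names(amounts))
  if (length(missing) > 0) {
    if (missing_policy == "strict") {
      stop("missing intake for configured group(s): ",
           paste(missing, collapse = ", "),
           " (use missing_policy = 'impute_zero' or 'rescale' to proceed)",
           call. = FALSE)
    }
    if (missing_policy == "impute_zero") {
      warning("imputing zero intake for missing group(s): ",
              paste(missing, collapse = ", "), call. = FALSE)
      amounts[missing] <- 0
    } else {
      groups <- groups[groups$name %in% names(amounts), , drop = FALSE]
    }
  }
  x <- as.numeric(amounts[groups$name])
  r <- groups$recommended_intake_g
  points <- .score_points(x, r, groups$category, config$yellow_tolerance)
  group_scores <- tibble::tibble(
    food_group = groups$name,
    category = groups$category,
    intake_g = x,
    reference_g = r,
    ratio = ifelse(r > 0, x / r, NA_real_),
    points = points
  )
  total <- sum(points)
  sub <- function(cat) sum(points[groups$category == cat])
  max_possible <- 2L * nrow(groups)
  total_rescaled <- NA_real_
  if (missing_policy == "rescale" && length(missing) > 0) {
    total_rescaled <- total * max_possible_score(config) / max_possible
  }
  structure(
    list(
      subject_id = subject_id,
      day = day,
      group_scores = group_scores,
      total = as.integer(total),
      green_subscore = as.integer(sub("green")),
      yellow_subscore = as.integer(sub("yellow")),
      red_subscore = as.integer(sub("red")),
      max_possible = as.integer(max_possible),
      total_rescaled = total_rescaled
    ),
    class = "nl_daily_score"
  )
}

#' @export
print.nl_daily_score <- function(x, ...) {
  cat("<nl_daily_score> subject ", x$subject_id, ", day ",
      format(x$day), ": total ", x$total, "/", x$max_possible,
      " (green ", x$green_subscore, ", yellow ", x$yellow_subscore,
      ", red ", x$red_subscore, ")\n", sep = "")
  invisible(x)
}

#' Points earned and attainable per traffic-light category
#'
#' Under the default configuration the category maxima are green 10 (5 groups),
#' yellow 14 (7 groups) and red 6 (3 groups).
#'
#' @param score An `nl_daily_score`.
#' @return A tibble with columns `category`, `earned`, `maximum`, one row per
#'   traffic-light category (in green/yellow/red order).
#' @export
category_subscores <- function(score) {
  stopifnot(inherits(score, "nl_daily_score"))
  gs <- score$group_scores
  cat_f <- factor(gs$category, levels = .nl_categories)
  tibble::tibble(
    category = .nl_categories,
    earned = as.integer(tapply(gs$points, cat_f, sum, default = 0L)),
    maximum = as.integer(2L * tabulate(cat_f, nbins = 3L))
  )
}

#' Balance of earned points across traffic-light categories
#'
#' A day can reach a given total through very different category profiles; the
#' balance index summarises how closely the earned points are spread across
#' green, yellow and red in proportion to what each category can contribute.
#' With `p_c` the share of earned points in category `c` and `q_c` the share
#' of the attainable maximum held by `c`,
#' `B = 1 - (1/2) * sum_c |p_c - q_c|`, the complement of the total-variation
#' distance between the two proportions. `B = 1` iff points are earned in
#' exactly the proportions of the maxima; `B` approaches 0 when all points
#' come from a category holding a small share of the maximum. Undefined
#' (returns `NA`) when no points were earned.
#'
#' @param score An `nl_daily_score`.
#' @return A number in `[0, 1]`, or `NA_real_` when `total = 0`.
#' @export
balance_index <- function(score) {
  stopifnot(inherits(score, "nl_daily_score"))
  if (score$total == 0) {
    return(NA_real_)
  }
  sub <- category_subscores(score)
  p <- sub$earned / score$total
  q <- sub$maximum / sum(sub$maximum)
  1 - sum(abs(p - q)) / 2
}

#' Score a table of subject-day intake records
#'
#' The batch interface over [score_day()]: takes the long intake layout
#' produced by [read_intakes()] or [generate_population()] and returns both a
#' per-day summary and the full per-group detail.
#'
#' @param intakes A data frame with columns `subject_id`, `day`, `food_group`,
#'   `amount_g`.
#' @param config An `nl_config`.
#' @param missing_policy Passed to [score_day()].
#' @return An object of class `nl_score_set`: a list of two tibbles,
#'   `summary` (one row per subject-day: `subject_id`, `day`, `total`,
#'   `green_subscore`, `yellow_subscore`, `red_subscore`, `max_possible`,
#'   `balance`, `total_rescaled`) and `per_group` (one row per subject-day and
#'   scored group).
#' @export
score_intakes <- function(intakes, config = default_config(),
                          missing_policy = c("strict", "impute_zero",
                                             "rescale")) {
  missing_policy <- match.arg(missing_policy)
  intakes <- tibble::as_tibble(intakes)
  required <- c("subject_id", "day", "food_group", "amount_g")
  missing_cols <- setdiff(required, names(intakes))
  if (length(missing_cols) > 0) {
    stop("intakes is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  keys <- dplyr::distinct(intakes, .data$subject_id, .data$day)
  keys <- dplyr::arrange(keys, .data$subject_id, .data$day)
  scored <- lapply(seq_len(nrow(keys)), function(i) {
    rows <- intakes[intakes$subject_id == keys$subject_id[i] &
                      intakes$day == keys$day[i], ]
    amounts <- stats::setNames(rows$amount_g, rows$food_group)
    score_day(daily_intake(keys$subject_id[i], keys$day[i], amounts),
              config = config, missing_policy = missing_policy)
  })
  summary <- dplyr::bind_rows(lapply(scored, function(s) {
    tibble::tibble(
      subject_id = s$subject_id, day = s$day, total = s$total,
      green_subscore = s$green_subscore, yellow_subscore = s$yellow_subscore,
      red_subscore = s$red_subscore, max_possible = s$max_possible,
      balance = balance_index(s), total_rescaled = s$total_rescaled
    )
  }))
  per_group <- dplyr::bind_rows(lapply(scored, function(s) {
    dplyr::mutate(s$group_scores, subject_id = s$subject_id, day = s$day,
                  .before = 1)
  }))
  structure(list(summary = summary, per_group = per_group),
            class = "nl_score_set")
}

#' @export
print.nl_score_set <- function(x, ...) {
  cat("<nl_score_set> ", nrow(x$summary), " subject-days, ",
      length(unique(x$summary$subject_id)), " subject(s)\n", sep = "")
  print(x$summary)
  invisible(x)
}
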