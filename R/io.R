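#' Read dietary intake records from CSV
#'
#' Accepts the two layouts common in dietary-record exports. The long layout
#' has columns `subject_id`, `day`, `food_group`, `amount_g`; the wide layout
#' has `subject_id`, `day` and one column per food group. `day` may be an
#' integer index or an ISO-8601 date; dates are converted to days since each
#' subject's first observation so both styles yield a numeric, ordered index.
#' Multiple rows for the same (subject, day, group) — multiple eating
#' occasions — are summed, with a notice. The dialect is fixed: comma
#' separator, decimal point, UTF-8, mandatory header.
#'
#' @param path Path to a CSV file.
#' @param layout `"long"` or `"wide"`.
#' @return A tibble in long layout: `subject_id` (character), `day` (numeric
#'   index), `food_group`, `amount_g`.
#' @export
read_intakes <- function(path, layout = c("long", "wide")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) {
    stop("intake file not found: ", path, call. = FALSE)
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (layout == "long") {
    required <- c("subject_id", "day", "food_group", "amount_g")
    missing_cols <- setdiff(required, names(raw))
    if (length(missing_cols) > 0) {
      stop("long intake file is missing column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    long <- raw[, required]
  } else {
    required <- c("subject_id", "day")
    missing_cols <- setdiff(required, names(raw))
    if (length(missing_cols) > 0) {
      stop("wide intake file is missing column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    long <- tidyr::pivot_longer(raw, cols = -dplyr::all_of(required),
                                names_to = "food_group",
                                values_to = "amount_g")
  }
  amounts <- suppressWarnings(as.numeric(long$amount_g))
  bad <- which(!is.na(long$amount_g) & is.na(amounts))
  if (length(bad) > 0) {
    stop("unparseable amount_g value '", long$amount_g[bad[1]],
         "' in data row ", bad[1], " of ", path, call. = FALSE)
  }
  if (anyNA(amounts)) {
    bad <- which(is.na(amounts))
    stop("missing amount_g in data row ", bad[1], " of ", path, call. = FALSE)
  }
  neg <- which(amounts < 0)
  if (length(neg) > 0) {
    stop("negative amount_g (", amounts[neg[1]], ") in data row ", neg[1],
         " of ", path, call. = FALSE)
  }
  long$amount_g <- amounts
  long$day <- .parse_day(long$day, long$subject_id, path)
  n_before <- nrow(long)
  long <- dplyr::summarise(
    dplyr::group_by(long, .data$subject_id, .data$day, .data$food_group),
    amount_g = sum(.data$amount_g), .groups = "drop"
  )
  if (nrow(long) < n_before) {
    message("read_intakes: summed ", n_before - nrow(long),
            " duplicate (subject, day, group) row(s) in ", path)
  }
  dplyr::arrange(long, .data$subject_id, .data$day, .data$food_group)
}

# integer indices pass through; ISO dates become days since the subject's
# first observation
.parse_day <- function(day, subject_id, path) {
  as_num <- suppressWarnings(as.numeric(day))
  as_date <- suppressWarnings(as.Date(day, format = "%Y-%m-%d"))
  bad <- which(is.na(as_num) & is.na(as_date))
  if (length(bad) > 0) {
    stop("unparseable day value '", day[bad[1]], "' in data row ", bad[1],
         " of ", path, " (expected integer index or YYYY-MM-DD)",
         call. = FALSE)
  }
  if (!anyNA(as_num)) {
    if (any(as_num < 0) || any(as_num != round(as_num))) {
      stop("day must be a non-negative integer index or an ISO-8601 date in ",
           path, call. = FALSE)
    }
    return(as_num)
  }
  if (anyNA(as_date)) {
    stop("day column mixes integer indices and dates in ", path,
         call. = FALSE)
  }
  stats::ave(as.numeric(as_date), subject_id, FUN = function(d) d - min(d))
}

#' Aggregate food-item intakes into food-group amounts
#'
#' Dietary records are often captured at the food-item level ("apple",
#' "rye bread"); scoring needs food-group amounts. Each item row contributes
#' `grams * edible_fraction` to the group it maps to; contributions are summed
#' per (subject, day, group), so the result is independent of row order.
#'
#' @param item_intakes Data frame with columns `subject_id`, `day`, `item`,
#'   `grams`.
#' @param mapping Data frame with columns `item_name`, `food_group` and
#'   optional `edible_fraction` in `(0, 1]` (default 1). `item_name` must be
#'   unique.
#' @param unmapped `"error"` (default) stops on any item absent from the
#'   mapping, naming it; `"drop"` discards such rows with a warning.
#' @param config Optional `nl_config`; when given, every mapped `food_group`
#'   must exist in it.
#' @return A long intake tibble (`subject_id`, `day`, `food_group`,
#'   `amount_g`).
#' @export
map_items_to_groups <- function(item_intakes, mapping,
                                unmapped = c("error", "drop"),
                                config = NULL) {
  unmapped <- match.arg(unmapped)
  item_intakes <- tibble::as_tibble(item_intakes)
  mapping <- tibble::as_tibble(mapping)
  for (col in c("subject_id", "day", "item", "grams")) {
    if (!col %in% names(item_intakes)) {
      stop("item_intakes is missing column '", col, "'", call. = FALSE)
    }
  }
  for (col in c("item_name", "food_group")) {
    if (!col %in% names(mapping)) {
      stop("mapping is missing column '", col, "'", call. = FALSE)
    }
  }
  if (!"edible_fraction" %in% names(mapping)) {
    mapping$edible_fraction <- 1
  }
  dup <- unique(mapping$item_name[duplicated(mapping$item_name)])
  if (length(dup) > 0) {
    stop("mapping has duplicate item_name(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (any(mapping$edible_fraction <= 0 | mapping$edible_fraction > 1)) {
    stop("edible_fraction must be in (0, 1]", call. = FALSE)
  }
  if (!is.null(config)) {
    stopifnot(inherits(config, "nl_config"))
    alien <- setdiff(mapping$food_group, config$groups$name)
    if (length(alien) > 0) {
      stop("mapping refers to group(s) not in the configuration: ",
           paste(alien, collapse = ", "), call. = FALSE)
    }
  }
  unknown <- setdiff(item_intakes$item, mapping$item_name)
  if (length(unknown) > 0) {
    if (unmapped == "error") {
      stop("unmapped item(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    warning("dropping ", sum(item_intakes$item %in% unknown),
            " row(s) with unmapped item(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
    item_intakes <- item_intakes[!item_intakes$item %in% unknown, ]
  }
  joined <- dplyr::inner_join(item_intakes, mapping,
                              by = c(item = "item_name"))
  out <- dplyr::summarise(
    dplyr::group_by(joined, .data$subject_id, .data$day, .data$food_group),
    amount_g = sum(.data$grams * .data$edible_fraction), .groups = "drop"
  )
  dplyr::arrange(out, .data$subject_id, .data$day, .data$food_group)
}

#' Write scores to CSV
#'
#' Two layouts: `"summary"` writes one row per subject-day (total, category
#' subscores, attainable maximum, balance index); `"per_group"` writes one row
#' per subject-day and food group (intake, reference, ratio, points). Totals
#' and points are written as integers and ratios/balance at 6 decimals, and
#' [read_scores()] reproduces those numbers exactly.
#'
#' @param scores An `nl_score_set` from [score_intakes()].
#' @param path Output CSV path.
#' @param detail `"summary"` or `"per_group"`.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path, detail = c("summary", "per_group")) {
  detail <- match.arg(detail)
  stopifnot(inherits(scores, "nl_score_set"))
  out <- if (detail == "summary") {
    dplyr::mutate(scores$summary,
                  balance = round(.data$balance, 6),
                  total_rescaled = round(.data$total_rescaled, 6))
  } else {
    dplyr::mutate(scores$per_group, ratio = round(.data$ratio, 6))
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a summary score CSV back
#'
#' The inverse of `write_scores(..., detail = "summary")`; used by the
#' aggregation command so that scoring and longitudinal analysis can run as
#' separate steps.
#'
#' @param path Path to a summary CSV written by [write_scores()].
#' @return The summary tibble.
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) {
    stop("score file not found: ", path, call. = FALSE)
  }
  out <- readr::read_csv(
    path,
    col_types = readr::cols(subject_id = "c", .default = "d"),
    progress = FALSE
  )
  for (col in intersect(names(out), c("total", "green_subscore",
                                      "yellow_subscore", "red_subscore",
                                      "max_possible"))) {
    out[[col]] <- as.integer(out[[col]])
  }
  required <- c("subject_id", "day", "total")
  missing_cols <- setdiff(required, names(out))
  if (length(missing_cols) > 0) {
    stop("score file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out
}
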