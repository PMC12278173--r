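#' Construct a food-group specification
#'
#' One row of a NutriLight configuration: a food group's identity, its
#' traffic-light category and the recommended daily amount `R` (g/day) that
#' observed intakes are scored against.
#'
#' @param name Unique text identifier (e.g. `"whole_grains"`).
#' @param category One of `"green"`, `"yellow"`, `"red"`.
#' @param recommended_intake_g Recommended amount in g/day. Must be
#'   non-negative; green and yellow groups additionally require a strictly
#'   positive value because their scoring rules are undefined at `R = 0`.
#' @param display_label Human-readable label; defaults to `name`.
#'
#' @return A one-row tibble with columns `name`, `category`,
#'   `recommended_intake_g`, `display_label`.
#' @export
#' @examples
#' food_group("nuts", "green", 50)
food_group <- function(name, category, recommended_intake_g,
                       display_label = name) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!category %in% .nl_categories) {
    stop("category must be one of ", paste(.nl_categories, collapse = ", "),
         ", got '", category, "' for group '", name, "'", call. = FALSE)
  }
  if (!is.numeric(recommended_intake_g) || length(recommended_intake_g) != 1L ||
      is.na(recommended_intake_g)) {
    stop("recommended_intake_g must be a single number for group '", name, "'",
         call. = FALSE)
  }
  tibble::tibble(
    name = name,
    category = category,
    recommended_intake_g = as.numeric(recommended_intake_g),
    display_label = display_label
  )
}

#' Construct a NutriLight scoring configuration
#'
#' Bundles the food-group table with the reference energy intake (the
#' assumption behind the shipped recommended amounts) and the yellow
#' "meeting" tolerance.
#'
#' @param groups A data frame with columns `name`, `category`,
#'   `recommended_intake_g` and optionally `display_label` — e.g. built by
#'   row-binding [food_group()] calls.
#' @param reference_energy_kcal Reference energy intake in kcal/day the
#'   recommended amounts are expressed at (default 2500, a moderately active
#'   adult).
#' @param yellow_tolerance Relative half-width of the yellow 2-point band
#'   around `R`, in `[0, 0.5)`. The default 0 scores yellow groups with 2
#'   points only at `x = R` exactly (within floating-point tolerance); 0.1 is
#'   a pragmatic choice for continuous real-world intake data.
#'
#' @return An object of class `nl_config`.
#' @seealso [default_config()], [validate_config()], [load_config()]
#' @export
nutrilight_config <- function(groups, reference_energy_kcal = 2500,
                              yellow_tolerance = 0) {
  groups <- tibble::as_tibble(groups)
  required <- c("name", "category", "recommended_intake_g")
  missing_cols <- setdiff(required, names(groups))
  if (length(missing_cols) > 0) {
    stop("groups is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"display_label" %in% names(groups)) {
    groups$display_label <- groups$name
  }
  groups <- groups[, c(required, "display_label")]
  groups$name <- as.character(groups$name)
  groups$category <- as.character(groups$category)
  groups$recommended_intake_g <- as.numeric(groups$recommended_intake_g)
  if (!is.numeric(reference_energy_kcal) || length(reference_energy_kcal) != 1L) {
    stop("reference_energy_kcal must be a single number", call. = FALSE)
  }
  if (!is.numeric(yellow_tolerance) || length(yellow_tolerance) != 1L) {
    stop("yellow_tolerance must be a single number", call. = FALSE)
  }
  structure(
    list(
      groups = groups,
      reference_energy_kcal = as.numeric(reference_energy_kcal),
      yellow_tolerance = as.numeric(yellow_tolerance)
    ),
    class = "nl_config"
  )
}

#' @export
print.nl_config <- function(x, ...) {
  counts <- table(factor(x$groups$category, levels = .nl_categories))
  cat("<nl_config> ", nrow(x$groups), " food groups (",
      counts[["green"]], " green, ", counts[["yellow"]], " yellow, ",
      counts[["red"]], " red), max score ", max_possible_score(x), "\n",
      "  reference energy: ", x$reference_energy_kcal, " kcal/day",
      " | yellow tolerance: ", x$yellow_tolerance, "\n", sep = "")
  print(x$groups, n = nrow(x$groups))
  invisible(x)
}

# cache for the shipped default, filled on first use
.nl_state <- new.env(parent = emptyenv())

#' The shipped default configuration
#'
#' Fifteen food groups — 5 green (whole grains, vegetables, fruits, soy and
#' legumes, nuts), 7 yellow (refined grains, poultry, dairy foods, eggs, fish
#' and seafood, plant oils, starchy vegetables) and 3 red (red meat, animal
#' oils, added sugars) — with recommended daily amounts taken from the
#' EAT-Lancet reference diet at 2500 kcal/day. The maximum attainable total is
#' 30 points. The values ship in a commented YAML file
#' (`system.file("extdata", "nutrilight_default.yaml", package = "nutrilight")`)
#' intended as a template for regional adaptation.
#'
#' @return An `nl_config` with 15 groups.
#' @export
#' @examples
#' cfg <- default_config()
#' max_possible_score(cfg)
default_config <- function() {
  if (is.null(.nl_state$default_config)) {
    path <- system.file("extdata", "nutrilight_default.yaml",
                        package = "nutrilight", mustWork = TRUE)
    .nl_state$default_config <- load_config(path)
  }
  .nl_state$default_config
}

#' Validate a configuration
#'
#' Checks every invariant of the configuration and returns the violations as
#' data rather than throwing: unique group names, a known traffic-light
#' category per group, non-negative recommended amounts (strictly positive for
#' green and yellow groups), positive reference energy, and a yellow tolerance
#' in `[0, 0.5)`. A non-default group count is not a violation — the maximum
#' score simply scales as twice the number of groups.
#'
#' @param config An `nl_config`.
#' @return A tibble with columns `group` (`NA` for config-level rules), `rule`
#'   and `message`; zero rows when the configuration is valid.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "nl_config"))
  g <- config$groups
  bad <- tibble::tibble(group = character(), rule = character(),
                        message = character())
  add <- function(group, rule, message) {
    bad <<- tibble::add_row(bad, group = group, rule = rule, message = message)
  }
  dup <- unique(g$name[duplicated(g$name)])
  for (d in dup) {
    add(d, "unique_name", paste0("duplicate group name '", d, "'"))
  }
  for (i in seq_len(nrow(g))) {
    nm <- g$name[i]
    if (!g$category[i] %in% .nl_categories) {
      add(nm, "category",
          paste0("group '", nm, "' has unknown category '", g$category[i], "'"))
    }
    r <- g$recommended_intake_g[i]
    if (is.na(r) || r < 0) {
      add(nm, "nonnegative_intake",
          paste0("group '", nm, "' has negative recommended_intake_g (", r, ")"))
    } else if (r == 0 && g$category[i] %in% c("green", "yellow")) {
      add(nm, "positive_intake",
          paste0("group '", nm, "' (", g$category[i],
                 ") requires recommended_intake_g > 0; scoring is undefined at R = 0"))
    }
  }
  if (is.na(config$reference_energy_kcal) || config$reference_energy_kcal <= 0) {
    add(NA_character_, "reference_energy",
        paste0("reference_energy_kcal must be > 0, got ",
               config$reference_energy_kcal))
  }
  tau <- config$yellow_tolerance
  if (is.na(tau) || tau < 0 || tau >= 0.5) {
    add(NA_character_, "yellow_tolerance",
        paste0("yellow_tolerance must be in [0, 0.5), got ", tau))
  }
  bad
}

#' Load a configuration from JSON or YAML
#'
#' The file format is detected from the extension (`.json` vs
#' `.yaml`/`.yml`). Schema: top-level keys `reference_energy_kcal` (number),
#' `yellow_tolerance` (number) and `groups`, a list of records with keys
#' `name`, `category` (green/yellow/red), `recommended_intake_g` and optional
#' `display_label`. Loading then saving then loading is the identity on all
#' fields.
#'
#' @param path Path to a JSON or YAML configuration file (UTF-8).
#' @return A validated `nl_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    stop("unrecognised config format '", ext, "' (expected .json, .yaml or .yml)",
         call. = FALSE)
  }
  if (is.null(raw$groups) || length(raw$groups) == 0) {
    stop("config file has no 'groups' entry: ", path, call. = FALSE)
  }
  rows <- lapply(raw$groups, function(gr) {
    for (key in c("name", "category", "recommended_intake_g")) {
      if (is.null(gr[[key]])) {
        stop("config group entry is missing field '", key, "'",
             if (!is.null(gr$name)) paste0(" (group '", gr$name, "')") else "",
             call. = FALSE)
      }
    }
    food_group(gr$name, gr$category, gr$recommended_intake_g,
               display_label = gr$display_label %||% gr$name)
  })
  config <- nutrilight_config(
    groups = dplyr::bind_rows(rows),
    reference_energy_kcal = raw$reference_energy_kcal %||% 2500,
    yellow_tolerance = raw$yellow_tolerance %||% 0
  )
  violations <- validate_config(config)
  if (nrow(violations) > 0) {
    stop("invalid config '", path, "':\n  ",
         paste(violations$message, collapse = "\n  "), call. = FALSE)
  }
  config
}

#' Save a configuration to JSON or YAML
#'
#' Writes the schema documented in [load_config()]; the format follows the
#' file extension unless `format` overrides it.
#'
#' @param config An `nl_config`.
#' @param path Output path.
#' @param format `"auto"` (from extension), `"json"` or `"yaml"`.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path, format = c("auto", "json", "yaml")) {
  stopifnot(inherits(config, "nl_config"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "json") "json" else "yaml"
  }
  payload <- list(
    reference_energy_kcal = config$reference_energy_kcal,
    yellow_tolerance = config$yellow_tolerance,
    groups = lapply(seq_len(nrow(config$groups)), function(i) {
      g <- config$groups[i, ]
      list(
        name = g$name,
        category = g$category,
        recommended_intake_g = g$recommended_intake_g,
        display_label = g$display_label
      )
    })
  )
  if (format == "json") {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(payload, path, precision = 15)
  }
  invisible(path)
}

#' Rescale recommended amounts to a subject's energy intake
#'
#' The shipped recommendations assume a 2500 kcal/day diet. For subjects with
#' a different energy intake, every recommended amount is scaled by
#' `subject_energy_kcal / reference_energy_kcal`; names, categories and the
#' reference energy itself are unchanged, so adjustments compose
#' multiplicatively. Energy adjustment is never applied implicitly — callers
#' opt in.
#'
#' @param config An `nl_config`.
#' @param subject_energy_kcal The subject's energy intake in kcal/day (> 0).
#' @return A new `nl_config` with scaled `recommended_intake_g`.
#' @export
#' @examples
#' cfg <- default_config()
#' half <- adjust_for_energy(cfg, 1250)
#' all.equal(half$groups$recommended_intake_g,
#'           cfg$groups$recommended_intake_g / 2)
adjust_for_energy <- function(config, subject_energy_kcal) {
  stopifnot(inherits(config, "nl_config"))
  if (!is.numeric(subject_energy_kcal) || length(subject_energy_kcal) != 1L ||
      is.na(subject_energy_kcal) || subject_energy_kcal <= 0) {
    stop("subject_energy_kcal must be a single positive number", call. = FALSE)
  }
  out <- config
  out$groups$recommended_intake_g <-
    config$groups$recommended_intake_g *
    (subject_energy_kcal / config$reference_energy_kcal)
  out
}

#' Maximum attainable total score
#'
#' Each group contributes at most 2 points, so the maximum is twice the number
#' of configured groups: 30 for the default 15-group configuration.
#'
#' @param config An `nl_config`.
#' @return An integer.
#' @export
max_possible_score <- function(config) {
  stopifnot(inherits(config, "nl_config"))
  2L * nrow(config$groups)
}
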