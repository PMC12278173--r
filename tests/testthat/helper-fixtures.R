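# Named intake vectors hitting chosen bands of every group's rule.
ideal_amounts <- function(config = default_config()) {
  with(config$groups, stats::setNames(
    ifelse(category == "red", recommended_intake_g / 2, recommended_intake_g),
    name))
}

zero_amounts <- function(config = default_config()) {
  stats::setNames(rep(0, nrow(config$groups)), config$groups$name)
}

# long-layout intake tibble for a fixed set of per-day amounts
amounts_to_long <- function(amounts, subject_id = "S1", day = 1) {
  tibble::tibble(subject_id = subject_id, day = day,
                 food_group = names(amounts), amount_g = unname(amounts))
}

# small arbitrary config used where the default's 15 groups are overkill
toy_config <- function(yellow_tolerance = 0) {
  nutrilight_config(
    dplyr::bind_rows(
      food_group("leafy", "green", 100),
      food_group("grain", "yellow", 200),
      food_group("sweets", "red", 25)
    ),
    yellow_tolerance = yellow_tolerance
  )
}
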