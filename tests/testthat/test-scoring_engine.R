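test_that("green rule follows the encouraged-food bands", {
  expect_identical(score_green(300, 300), 2L)   # meets recommendation
  expect_identical(score_green(150, 300), 1L)   # partial intake
  expect_identical(score_green(0, 300), 0L)     # absent
  expect_identical(score_green(450, 300), 2L)   # exceeding keeps full points
  expect_error(score_green(100, 0), "> 0")
  expect_error(score_green(-1, 100), "non-negative")
})

test_that("yellow rule follows the moderation bands", {
  expect_identical(score_yellow(250, 250), 2L)       # on target
  expect_identical(score_yellow(375, 250), 1L)       # R < x < 2R
  expect_identical(score_yellow(125, 250), 1L)       # 0 < x < R
  expect_identical(score_yellow(0, 250), 0L)         # under-consumed
  expect_identical(score_yellow(500, 250), 0L)       # x = 2R overconsumed
  expect_identical(score_yellow(600, 250), 0L)
  expect_error(score_yellow(100, 100, tolerance = 0.5), "0.5")
  expect_error(score_yellow(100, 100, tolerance = -0.1), "0.5")
})

test_that("yellow tolerance widens the 2-point band symmetrically", {
  # tau = 0.1: [0.9R, 1.1R] earns 2
  expect_identical(score_yellow(c(89, 90, 100, 110, 111), 100,
                                tolerance = 0.1),
                   c(1L, 2L, 2L, 2L, 1L))
})

test_that("red rule follows the limited-food bands", {
  expect_identical(score_red(7, 14), 2L)    # within the limit
  expect_identical(score_red(0, 14), 2L)    # zero is within the limit
  expect_identical(score_red(14, 14), 2L)   # boundary belongs to 'within'
  expect_identical(score_red(21, 14), 1L)   # slightly exceeding
  expect_identical(score_red(28, 14), 0L)   # x = 2R is excess
  expect_identical(score_red(42, 14), 0L)
  # limiting case R = 0: the 1-point band is empty
  expect_identical(score_red(0, 0), 2L)
  expect_identical(score_red(0.1, 0), 0L)
})

test_that("boundary behaviour survives floating-point arithmetic", {
  r <- 1 / 3
  expect_identical(score_green(sum(rep(r / 10, 10)), r), 2L)
  expect_identical(score_yellow(sum(rep(r / 10, 10)), r), 2L)
  expect_identical(score_red(2 * sum(rep(r / 10, 10)), r), 0L)
})

test_that("score_group dispatches on category and fills the record", {
  gs <- score_group(300, food_group("vegetables", "green", 300))
  expect_identical(gs$points, 2L)
  expect_equal(gs$ratio, 1.0)
  expect_identical(score_group(0, food_group("red_meat", "red", 14))$points,
                   2L)
  expect_identical(score_group(56, food_group("fish", "yellow", 28))$points,
                   0L)
  bad <- food_group("x", "green", 10)
  bad$category <- "purple"
  expect_error(score_group(5, bad), "purple")
})

test_that("an ideal day attains the maximum and an empty day scores 6", {
  cfg <- default_config()
  ideal <- score_day(ideal_amounts(cfg), cfg)
  expect_identical(ideal$total, 30L)
  expect_identical(ideal$max_possible, 30L)
  expect_identical(c(ideal$green_subscore, ideal$yellow_subscore,
                     ideal$red_subscore), c(10L, 14L, 6L))

  # at zero intake only the three red groups score (2 points each)
  zero <- score_day(zero_amounts(cfg), cfg)
  expect_identical(zero$total, 6L)
  expect_identical(c(zero$green_subscore, zero$yellow_subscore,
                     zero$red_subscore), c(0L, 0L, 6L))
})

test_that("missing-group policies behave as documented", {
  cfg <- default_config()
  partial <- ideal_amounts(cfg)[-match("nuts", cfg$groups$name)]

  expect_error(score_day(partial, cfg), "nuts")
  expect_warning(s <- score_day(partial, cfg, missing_policy = "impute_zero"),
                 "nuts")
  expect_identical(s$total, 28L)  # nuts imputed to zero: 0 points instead of 2
  s2 <- score_day(partial, cfg, missing_policy = "rescale")
  expect_identical(s2$max_possible, 28L)
  expect_identical(s2$total, 28L)
  expect_equal(s2$total_rescaled, 28 * 30 / 28)

  stranger <- c(ideal_amounts(cfg), chocolate = 10)
  expect_error(score_day(stranger, cfg), "chocolate")
})

test_that("max_possible_score is twice the group count", {
  expect_identical(max_possible_score(default_config()), 30L)
  expect_identical(max_possible_score(toy_config()), 6L)
  empty <- nutrilight_config(default_config()$groups[0, ])
  expect_identical(max_possible_score(empty), 0L)
  cfg14 <- nutrilight_config(default_config()$groups[-1, ])
  expect_identical(max_possible_score(cfg14), 28L)
})

test_that("category subscores report earned and attainable points", {
  cfg <- default_config()
  sub <- category_subscores(score_day(ideal_amounts(cfg), cfg))
  expect_equal(sub$earned, c(10L, 14L, 6L))
  expect_equal(sub$maximum, c(10L, 14L, 6L))
  sub0 <- category_subscores(score_day(zero_amounts(cfg), cfg))
  expect_equal(sub0$earned, c(0L, 0L, 6L))
  expect_equal(sub0$maximum, c(10L, 14L, 6L))
})

test_that("balance index measures proportionality of category points", {
  cfg <- default_config()
  expect_equal(balance_index(score_day(ideal_amounts(cfg), cfg)), 1)
  # all earned points from red only: B = 1 - (10/30 + 14/30 + 24/30)/2 = 0.2
  expect_equal(balance_index(score_day(zero_amounts(cfg), cfg)), 0.2)
  # no points at all: undefined
  worst <- zero_amounts(cfg)
  red <- cfg$groups$name[cfg$groups$category == "red"]
  worst[red] <- 10 * cfg$groups$recommended_intake_g[match(red, cfg$groups$name)]
  expect_identical(balance_index(score_day(worst, cfg)), NA_real_)
})

test_that("engine matches the brute-force interval oracle on a dense grid", {
  for (tau in c(0, 0.1)) {
    grid <- sort(unique(c(seq(0, 4, by = 0.01), 1 - tau, 1 + tau)))
    for (cat in c("green", "yellow", "red")) {
      expected <- vapply(grid, oracle_points, integer(1), category = cat,
                         tau = tau)
      for (r in c(1, 14, 232)) {
        got <- engine_points(grid * r, r, cat, tau = tau)
        expect_identical(got, expected,
                         info = paste("category", cat, "r", r, "tau", tau))
      }
    }
  }
})

test_that("rules are scale-invariant and totals partition across categories", {
  cfg <- default_config()
  withr::local_seed(99)
  for (i in 1:200) {
    x <- runif(1, 0, 5)
    r <- runif(1, 0.1, 500)
    k <- runif(1, 0.01, 100)
    for (cat in c("green", "yellow", "red")) {
      expect_identical(engine_points(k * x * r, k * r, cat),
                       engine_points(x * r, r, cat))
    }
    amounts <- stats::setNames(
      runif(15, 0, 3) * cfg$groups$recommended_intake_g, cfg$groups$name)
    s <- score_day(amounts, cfg)
    expect_true(all(s$group_scores$points %in% 0:2))
    expect_identical(s$total,
                     s$green_subscore + s$yellow_subscore + s$red_subscore)
    expect_true(s$total >= 0L && s$total <= s$max_possible)
  }
})

test_that("rules are monotone in the documented directions", {
  xs <- seq(0, 600, by = 1.5)
  g <- score_green(xs, 200)
  expect_true(all(diff(g) >= 0))
  r <- score_red(xs, 200)
  expect_true(all(diff(r) <= 0))
  y <- score_yellow(xs, 200)
  expect_identical(which(y == 2L), which(xs == 200))
  expect_identical(y[xs == 0], 0L)
  expect_true(all(y[xs >= 400] == 0L))
})

test_that("any diet meeting every recommendation scores the maximum", {
  cfg <- default_config()
  withr::local_seed(7)
  for (i in 1:20) {
    g <- cfg$groups
    amounts <- stats::setNames(ifelse(
      g$category == "green", g$recommended_intake_g * runif(15, 1, 4),
      ifelse(g$category == "yellow", g$recommended_intake_g,
             g$recommended_intake_g * runif(15, 0, 1))), g$name)
    expect_identical(score_day(amounts, cfg)$total, 30L)
  }
})

test_that("score_intakes batches subject-days with summary and detail", {
  cfg <- default_config()
  long <- dplyr::bind_rows(
    amounts_to_long(ideal_amounts(cfg), "A", 1),
    amounts_to_long(zero_amounts(cfg), "A", 2),
    amounts_to_long(ideal_amounts(cfg), "B", 1)
  )
  res <- score_intakes(long, cfg)
  expect_identical(nrow(res$summary), 3L)
  expect_identical(res$summary$total, c(30L, 6L, 30L))
  expect_identical(nrow(res$per_group), 45L)
  expect_equal(res$summary$balance, c(1, 0.2, 1))
})
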