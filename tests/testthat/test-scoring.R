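test_that("margin bands reproduce the 120/138 s edges", {
  b <- margin_bands(120, 0.15)
  expect_equal(unname(b), c(120, 138))
  expect_equal(unname(margin_bands(100, 0)), c(100, 100))  # degenerate margin
  expect_error(margin_bands(-5, 0.15), "positive")
  expect_error(margin_bands(120, -0.1), "non-negative")
})

test_that("deviation bands rescale the cycle target to 18/36 s", {
  expect_equal(unname(deviation_bands(120, 0.15)), c(18, 36))
  rub <- default_rubric()
  expect_equal(rub$variables$dev_rhythm$score2_upper, 18)
  expect_equal(rub$variables$dev_rhythm$score1_upper, 36)
  expect_equal(rub$variables$dev_compressor_change$score1_upper, 36)
})

test_that("single-variable scores follow the rubric bands", {
  expect_identical(score_variable("no_flow_fraction", 14.06), 2L)
  expect_identical(score_variable("no_flow_fraction", 17), 1L)
  expect_identical(score_variable("no_flow_fraction", 21), 0L)
  expect_identical(score_variable("dev_rhythm", 31), 1L)
  expect_identical(score_variable("avg_depth", NA_real_), NA_integer_)
  expect_identical(score_variable("avg_depth", 5.4), 2L)
  expect_identical(score_variable("avg_depth", 4.4), 0L)
  expect_identical(score_variable("avg_rate", 110), 2L)
  expect_identical(score_variable("avg_rate", 130), 0L)
  expect_identical(score_variable("t_first_shock", NA_real_), 0L)  # never shocked
  expect_identical(score_variable("dev_adrenaline", 0), 2L)
  expect_identical(score_variable("dev_adrenaline", 5), 0L)  # no middle band
  expect_identical(score_variable("amiodarone_class", "AFTER_THIRD_SHOCK"), 2L)
  expect_identical(score_variable("amiodarone_class", "GIVEN"), 1L)
  expect_identical(score_variable("amiodarone_class", "NONE"), 0L)
  expect_error(score_variable("not_a_variable", 1), "does not define")
})

test_that("band edges are exact and scores are monotone in the value", {
  rub <- default_rubric()
  eps <- 1e-9
  for (v in c("no_flow_fraction", "t_first_rhythm", "t_first_shock",
              "dev_rhythm", "dev_compressor_change")) {
    e2 <- rub$variables[[v]]$score2_upper
    e1 <- rub$variables[[v]]$score1_upper
    expect_identical(score_variable(v, e2, rub), 2L)
    expect_identical(score_variable(v, e2 + eps, rub), 1L)
    expect_identical(score_variable(v, e1, rub), 1L)
    expect_identical(score_variable(v, e1 + eps, rub), 0L)
    # monotone: larger (worse) values never score higher
    vals <- sort(c(0, e2 / 2, e2, e2 + eps, (e2 + e1) / 2, e1, e1 + eps, 2 * e1))
    sc <- vapply(vals, function(x) score_variable(v, x, rub), integer(1))
    expect_true(all(diff(sc) <= 0))
  }
})

test_that("count scores compare observed with expected actions", {
  expect_identical(score_expected_count(7, 7), 2L)
  expect_identical(score_expected_count(9, 7), 2L)
  expect_identical(score_expected_count(6, 7), 1L)
  expect_identical(score_expected_count(0, 3), 0L)
  expect_error(score_expected_count(-1, 3), "non-negative")
})

test_that("the team score averages the non-missing variables", {
  expect_equal(score_card("A", perfect_scores())$cpr_score, 2.0)

  s <- perfect_scores()
  s[c("avg_depth", "avg_rate")] <- NA_integer_
  card <- score_card("B", s)
  expect_equal(card$cpr_score, 2.0)
  expect_identical(card$n_scored, 10L)

  s <- perfect_scores()
  s[PERFORMANCE_VARIABLES] <- c(2, 2, 2, 2, 2, 1, 1, 1, 1, 1, 0, 0)
  expect_equal(score_card("C", s)$cpr_score, 1.25)  # 15/12

  s[1:3] <- NA_integer_
  expect_error(score_card("D", s), "more than two missing")

  withr::with_seed(301, {
    for (i in 1:20) {
      s <- perfect_scores()
      s[] <- sample(0:2, 12, replace = TRUE)
      if (i %% 2 == 0) s[c("avg_depth", "avg_rate")] <- NA_integer_
      card <- score_card("R", s)
      expect_equal(card$cpr_score, mean(s, na.rm = TRUE))
      expect_identical(card$n_scored, sum(!is.na(s)))
    }
  })
})

test_that("a guideline-conform log with good compressions scores 2 everywhere", {
  log <- make_conform_log()
  series <- compression_series(log$team_id, data.frame(
    period_start = 0, period_end = 800, mean_depth = 5.4, mean_rate = 112))
  vars <- compute_performance(log, series)
  card <- score_team(vars)
  expect_equal(card$cpr_score, 2.0)
  expect_identical(card$n_scored, 12L)

  # without compression data the same team is scored on ten variables
  card10 <- score_team(compute_performance(log))
  expect_identical(card10$n_scored, 10L)
  expect_equal(card10$cpr_score, 2.0)
})

test_that("removing depth/rate preserves the ordering of identical remainders", {
  withr::with_seed(302, {
    for (i in 1:10) {
      s1 <- perfect_scores(); s1[] <- sample(0:2, 12, replace = TRUE)
      s2 <- perfect_scores(); s2[] <- sample(0:2, 12, replace = TRUE)
      s2[setdiff(PERFORMANCE_VARIABLES, c("avg_depth", "avg_rate"))] <-
        s1[setdiff(PERFORMANCE_VARIABLES, c("avg_depth", "avg_rate"))]
      r1 <- s1; r1[c("avg_depth", "avg_rate")] <- NA_integer_
      r2 <- s2; r2[c("avg_depth", "avg_rate")] <- NA_integer_
      expect_equal(score_card("a", r1)$cpr_score, score_card("b", r2)$cpr_score)
    }
  })
})

test_that("the cohort table reports per-score shares over non-missing teams", {
  cards <- c(
    lapply(1:20, function(i) score_card(paste0("N", i), perfect_scores(), "NO_APP")),
    lapply(21:31, function(i) {
      s <- perfect_scores(); s["no_flow_fraction"] <- if (i <= 26) 1L else 0L
      score_card(paste0("N", i), s, "NO_APP")
    }))
  tab <- cohort_table(cards)
  nf <- tab[tab$variable == "no_flow_fraction", ]
  expect_equal(nf$p2, 100 * 20 / 31, tolerance = 1e-12)
  expect_equal(round(nf$p2, 1), 64.5)

  # depth shares use only teams with compression data as denominator
  cards2 <- c(cards[1:5], lapply(1:5, function(i) {
    s <- perfect_scores(); s[c("avg_depth", "avg_rate")] <- NA_integer_
    score_card(paste0("M", i), s, "NO_APP")
  }))
  tab2 <- cohort_table(cards2)
  expect_identical(tab2$n[tab2$variable == "avg_depth"], 5L)
  expect_equal(tab2$p2[tab2$variable == "avg_depth"], 100)
})

test_that("score distributions imply the printed group means", {
  cal <- calibration_table()
  degenerate <- data.frame(variable = PERFORMANCE_VARIABLES,
                           p0 = 0, p1 = 0, p2 = 1)
  expect_equal(expected_cohort_score(degenerate, 30, 5), 2.0)

  ca <- cal$distributions[cal$distributions$group == "CA_APP", ]
  no <- cal$distributions[cal$distributions$group == "NO_APP", ]
  expect_equal(expected_cohort_score(ca, 32, 5), 1.47, tolerance = 0.01)
  expect_equal(expected_cohort_score(no, 31, 9), 1.24, tolerance = 0.01)

  bad <- degenerate; bad$p2[1] <- 0.5
  expect_error(expected_cohort_score(bad, 30, 5), "sum")
})

test_that("rubrics round-trip through the YAML configuration", {
  rub <- default_rubric()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_rubric(rub, path)
  back <- read_rubric(path)
  expect_equal(unclass(back), unclass(rub))
  # edited band edge takes effect
  txt <- readLines(path)
  hacked <- read_rubric(path)
  hacked$variables$no_flow_fraction$score2_upper <- 10
  expect_identical(score_variable("no_flow_fraction", 12, hacked), 1L)
})
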