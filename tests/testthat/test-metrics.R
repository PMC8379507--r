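test_that("no-flow fraction covers the hand-worked cases", {
  full <- event_log("T", "CA_APP", 0, 200, data.frame(
    kind = c("COMPRESSIONS_START", "COMPRESSIONS_STOP"), timestamp = c(0, 200)))
  expect_equal(no_flow_fraction(full), 0.0)

  paused <- event_log("T", "CA_APP", 0, 200, data.frame(
    kind = rep(c("COMPRESSIONS_START", "COMPRESSIONS_STOP"), 2),
    timestamp = c(0, 100, 130, 200)))
  expect_equal(no_flow_fraction(paused), 15.0)

  none <- event_log("T", "CA_APP", 0, 200,
                    data.frame(kind = character(), timestamp = numeric()))
  expect_equal(no_flow_fraction(none), 100.0)

  # ROSC truncates the arrest window
  rosc <- event_log("T", "CA_APP", 0, 200, data.frame(
    kind = c("COMPRESSIONS_START", "COMPRESSIONS_STOP", "ROSC"),
    timestamp = c(0, 100, 150)))
  expect_equal(no_flow_fraction(rosc), 100 * 50 / 150)
})

test_that("no-flow fraction agrees with a binning sweep on random logs", {
  withr::with_seed(202, {
    for (i in 1:60) {
      log <- random_valid_log()
      expect_equal(no_flow_fraction(log), no_flow_oracle(log), tolerance = 1e-6)
    }
  })
})

test_that("removing a pause never increases the no-flow fraction", {
  withr::with_seed(203, {
    for (i in 1:25) {
      log <- random_valid_log()
      comp <- log$events$kind %in% c("COMPRESSIONS_START", "COMPRESSIONS_STOP")
      idx <- which(comp)
      if (length(idx) < 4) next
      # merge the first two segments: drop the first stop and second start
      merged <- log
      merged$events <- merged$events[-idx[2:3], ]
      expect_lte(no_flow_fraction(merged), no_flow_fraction(log) + 1e-9)
    }
  })
})

test_that("time to first event subtracts arrival and handles absence", {
  log <- event_log("T", "NO_APP", 20, 300, data.frame(
    kind = c("RHYTHM_CHECK_START", "RHYTHM_CHECK_END"), timestamp = c(118, 121)))
  expect_equal(time_to_first(log, "RHYTHM_CHECK_START"), 98)
  expect_true(is.na(time_to_first(log, "DEFIBRILLATION")))

  zero <- event_log("T", "NO_APP", 0, 300, data.frame(
    kind = "DEFIBRILLATION", timestamp = 120))
  expect_equal(time_to_first(zero, "DEFIBRILLATION"), 120)
})

test_that("cycle deviation matches hand arithmetic and the loop oracle", {
  expect_equal(interval_deviation(c(120, 240, 360), 120)$mean_dev, 0)
  expect_equal(interval_deviation(c(120, 270, 400), 120)$mean_dev,
               mean(c(0, 30, 10)))
  one <- interval_deviation(140, 120, origin = 20)
  expect_equal(one$mean_dev, 0)
  expect_identical(one$n_events, 1L)
  empty <- interval_deviation(numeric(0), 120)
  expect_true(is.na(empty$mean_dev))
  expect_identical(empty$n_events, 0L)

  withr::with_seed(204, {
    for (i in 1:40) {
      ts <- sort(runif(sample(1:8, 1), 0, 1000))
      tgt <- runif(1, 60, 200)
      expect_equal(interval_deviation(ts, tgt)$mean_dev,
                   interval_deviation_oracle(ts, tgt))
    }
  })
})

test_that("delaying an event never decreases the mean cycle deviation", {
  withr::with_seed(205, {
    for (i in 1:25) {
      ts <- sort(runif(5, 0, 800))
      base <- interval_deviation(ts, 120)$mean_dev
      j <- sample(5, 1)
      delayed <- ts
      delayed[j:5] <- delayed[j:5] + runif(1, 1, 60)
      expect_gte(interval_deviation(delayed, 120)$mean_dev, base - 1e-12)
    }
  })
})

test_that("adrenaline deviations judge inter-dose intervals against 3-5 min", {
  expect_equal(adrenaline_deviation(c(100, 340, 700))$mean_dev, 30)
  expect_equal(adrenaline_deviation(c(0, 240, 480, 720))$mean_dev, 0)
  single <- adrenaline_deviation(300)
  expect_equal(single$mean_dev, 0)
  expect_identical(single$n_doses, 1L)
  # early doses are distance below the window
  expect_equal(adrenaline_deviation(c(0, 120))$mean_dev, 60)
})

test_that("expected action counts scale with scenario length", {
  expect_identical(expected_count(943, "rhythm_check"), 7L)
  expect_identical(expected_count(943, "compressor_change"), 7L)
  expect_identical(expected_count(943, "adrenaline"), 3L)
  expect_identical(expected_count(120, "rhythm_check"), 1L)
  expect_identical(expected_count(100, "rhythm_check"), 0L)
  expect_error(expected_count(0, "rhythm_check"), "positive")
})

test_that("amiodarone timing is classified against the third shock", {
  base <- function(amio_at, shocks = c(100, 220, 340)) {
    ev <- rbind(data.frame(kind = "DEFIBRILLATION", timestamp = shocks),
                if (!is.null(amio_at))
                  data.frame(kind = "AMIODARONE", timestamp = amio_at))
    event_log("T", "CA_APP", 0, 1000, ev)
  }
  expect_identical(amiodarone_class(base(350)), "AFTER_THIRD_SHOCK")
  expect_identical(amiodarone_class(base(50)), "GIVEN")
  expect_identical(amiodarone_class(base(NULL)), "NONE")
  # given only after the fourth shock is late: wrong-time "GIVEN"
  expect_identical(amiodarone_class(base(500, shocks = c(100, 220, 340, 460))),
                   "GIVEN")
})

test_that("compression quality averages are duration weighted", {
  one <- compression_series("T", data.frame(
    period_start = 0, period_end = 60, mean_depth = 5, mean_rate = 110))
  expect_equal(average_compression_quality(one), list(depth = 5, rate = 110))

  two <- compression_series("T", data.frame(
    period_start = c(0, 60), period_end = c(60, 180),
    mean_depth = c(4, 5.5), mean_rate = c(100, 130)))
  expect_equal(average_compression_quality(two), list(depth = 5, rate = 120))

  expect_equal(average_compression_quality(compression_series("T", available = FALSE)),
               list(depth = NA_real_, rate = NA_real_))
})

test_that("compute_performance populates all twelve variables coherently", {
  log <- make_conform_log()
  p <- compute_performance(log)
  expect_equal(p$dev_rhythm, 0)
  expect_equal(p$dev_compressor_change, 0)
  expect_equal(p$dev_adrenaline, 0)
  expect_lt(p$no_flow_fraction, 15)
  expect_identical(p$amiodarone_class, "AFTER_THIRD_SHOCK")
  expect_true(is.na(p$avg_depth))
  expect_equal(p$scenario_length, 800)

  noshock <- event_log("T", "NO_APP", 10, 400, data.frame(
    kind = c("COMPRESSIONS_START", "ADRENALINE"), timestamp = c(15, 200)))
  pn <- compute_performance(noshock)
  expect_true(is.na(pn$t_first_shock))
  expect_identical(pn$n_adrenaline, 1L)
  expect_equal(pn$dev_adrenaline, 0)

  empty <- event_log("T", "NO_APP", 10, 400,
                     data.frame(kind = character(), timestamp = numeric()))
  pe <- compute_performance(empty)
  expect_identical(pe$n_adrenaline, 0L)
  expect_equal(pe$dev_adrenaline, 0)
  expect_equal(pe$no_flow_fraction, 100)
})

test_that("performance is invariant to translating the whole record in time", {
  withr::with_seed(206, {
    for (i in 1:15) {
      log <- random_valid_log()
      shift <- runif(1, 5, 120)
      moved <- log
      moved$arrival_time <- log$arrival_time + shift
      moved$scenario_end <- log$scenario_end + shift
      moved$events$timestamp <- log$events$timestamp + shift
      if (!is.na(moved$rosc_time)) moved$rosc_time <- moved$rosc_time + shift
      a <- unclass(compute_performance(log))
      b <- unclass(compute_performance(moved))
      expect_equal(a[setdiff(names(a), "team_id")],
                   b[setdiff(names(b), "team_id")], tolerance = 1e-9)
    }
  })
})
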