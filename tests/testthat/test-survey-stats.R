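st_one <- sun_table(as.Date("2024-11-11") + 0:1)

test_that("diel classification uses the half-open [sunset, sunrise) night", {
  ts <- as.POSIXct(c("2024-11-11 17:45:00",   # exactly sunset -> night
                     "2024-11-11 17:46:00",
                     "2024-11-11 12:00:00",   # noon -> day
                     "2024-11-12 05:44:50",   # pre-dawn -> night
                     "2024-11-12 05:45:00"),  # exactly sunrise -> day
                   tz = "UTC")
  expect_identical(classify_diel(ts, st_one),
                   c("night", "night", "day", "night", "day"))
  expect_error(classify_diel(as.POSIXct("2030-01-01 10:00:00", tz = "UTC"),
                             st_one), "no sunrise/sunset entry")
})

test_that("effort aggregation conserves logged time and splits cells", {
  # one searcher, 1 h of contiguous reef-day samples -> reef/day = 1.0 h
  ts <- as.POSIXct("2024-11-11 10:00:00", tz = "UTC") + seq(0, 3590, by = 10)
  logs <- data.frame(searcher_id = "S01", timestamp = ts,
                     depth_m = rep(5.5, length(ts)), habitat = "reef")
  et <- aggregate_effort(logs, st_one)
  expect_equal(et$cells$hours[et$cells$habitat == "reef" &
                              et$cells$diel == "day"], 1.0)
  expect_equal(et$total_hours, 1.0)
  expect_equal(sum(et$cells$hours), et$total_hours)
  expect_equal(sum(et$time_histogram$hours), et$total_hours)
  expect_equal(sum(et$depth_histogram$hours), et$total_hours)
  # all depth effort in the [5, 6) m bin
  expect_equal(et$depth_histogram$depth_bin, 5)
  # duplicate samples for one searcher are an error
  expect_error(aggregate_effort(rbind(logs, logs[1, ]), st_one),
               "not time-sorted|duplicate")
  dup <- logs; dup$timestamp[2] <- dup$timestamp[1]
  expect_error(aggregate_effort(dup, st_one), "duplicate")
})

test_that("synthetic logs round-trip the effort specification", {
  spec <- effort_spec(seed = 42)
  sim <- simulate_dive_logs(spec)
  et <- aggregate_effort(sim)
  for (i in seq_len(nrow(spec$strata))) {
    want <- spec$strata$hours[i]
    got <- et$cells$hours[et$cells$habitat == spec$strata$habitat[i] &
                          et$cells$diel == spec$strata$diel[i]]
    expect_lt(abs(got - want), 10 / 3600 + 1e-9)  # within one 10-s sample
  }
  expect_equal(sum(et$cells$hours), et$total_hours)
  # splitting one searcher's log across files changes no totals
  logs <- sim$logs
  part1 <- logs[seq_len(1000), ]; part2 <- logs[-seq_len(1000), ]
  et2 <- aggregate_effort(rbind(part1, part2), sim$sun)
  expect_equal(et2$cells, et$cells)
})

test_that("per-searcher averaging divides the depth histogram", {
  sim <- simulate_dive_logs(effort_spec(seed = 9))
  tot <- aggregate_effort(sim)
  avg <- aggregate_effort(sim$logs, sim$sun, per_searcher_average = TRUE)
  expect_equal(avg$depth_histogram$hours * tot$n_searchers,
               tot$depth_histogram$hours)
})

test_that("expected counts transfer the discovery rate by effort", {
  expect_equal(round(expected_count(25, 38.2, 32.0), 1), 20.9)
  expect_equal(round(expected_count(25, 57.4, 12.7), 1), 5.5)
  expect_equal(expected_count(0, 38.2, 32.0), 0)
  expect_error(expected_count(25, 0, 32.0), "positive")
})

test_that("exact rate test reproduces the field-survey p-values", {
  # 0 by day (32.0 h) vs 25 by night (38.2 h): closed form (T2/(T1+T2))^25
  p_day <- exact_poisson_rate_test(0, 32.0, 25, 38.2, "deficit")$p.value
  expect_equal(p_day, (38.2 / 70.2)^25, tolerance = 1e-12)
  expect_equal(p_day, 2.47e-7, tolerance = 0.01)
  # 0 on muck (12.7 h) vs 25 on reef (57.4 h)
  p_muck <- exact_poisson_rate_test(0, 12.7, 25, 57.4, "deficit")$p.value
  expect_equal(p_muck, (57.4 / 70.1)^25, tolerance = 1e-12)
  expect_equal(p_muck, 0.007, tolerance = 0.05)
})

test_that("degenerate tails: empty total and full tail give p = 1", {
  for (alt in c("deficit", "excess", "two.sided"))
    expect_equal(exact_poisson_rate_test(0, 1, 0, 1, alt)$p.value, 1)
  expect_equal(exact_poisson_rate_test(25, 32.0, 0, 38.2, "deficit")$p.value, 1)
  expect_error(exact_poisson_rate_test(2.5, 1, 3, 1), "integers")
  expect_error(exact_poisson_rate_test(2, 0, 3, 1))
})

test_that("all tails match exhaustive enumeration for n <= 60", {
  T1 <- 32.0; T2 <- 38.2
  p <- T1 / (T1 + T2)
  for (n in c(0:25, 40, 60)) {
    pmf <- enum_binom_pmf(n, p)
    for (x1 in 0:n) {
      x2 <- n - x1
      expect_equal(
        exact_poisson_rate_test(x1, T1, x2, T2, "deficit")$p.value,
        sum(pmf[seq_len(x1 + 1L)]), tolerance = 1e-12)
      expect_equal(
        exact_poisson_rate_test(x1, T1, x2, T2, "excess")$p.value,
        sum(pmf[(x1 + 1L):(n + 1L)]), tolerance = 1e-12)
      expect_equal(
        exact_poisson_rate_test(x1, T1, x2, T2, "two.sided")$p.value,
        min(1, sum(pmf[pmf <= pmf[x1 + 1L] * (1 + 1e-7)])),
        tolerance = 1e-12)
    }
  }
})

test_that("one-sided tails agree with stats::poisson.test", {
  cases <- expand.grid(x1 = c(0, 3, 10), x2 = c(0, 5, 25),
                       T1 = c(12.7, 32.0), T2 = c(38.2, 57.4))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    if (cs$x1 + cs$x2 == 0) next
    expect_equal(
      exact_poisson_rate_test(cs$x1, cs$T1, cs$x2, cs$T2, "deficit")$p.value,
      stats::poisson.test(c(cs$x1, cs$x2), c(cs$T1, cs$T2),
                          alternative = "less")$p.value,
      tolerance = 1e-10)
  }
})

test_that("type-I error is controlled and power is near 1 at study scale", {
  # equal true rates at the campaign's exposures; 10,000 replicates
  set.seed(314)
  r <- 25 / 38.2
  x1 <- rpois(10000, r * 32.0)
  x2 <- rpois(10000, r * 38.2)
  pvals <- vapply(seq_along(x1), function(i)
    exact_poisson_rate_test(x1[i], 32.0, x2[i], 38.2, "deficit")$p.value,
    numeric(1))
  rate <- mean(pvals <= 0.05)
  expect_lte(rate, 0.055)   # exact test: conservative, never anti-conservative
  expect_gte(rate, 0.01)    # but not degenerate
  # true day rate 0, night expectation 25 (the study's scale): power >= 99%
  x2p <- rpois(10000, 25)
  pow <- mean(vapply(x2p, function(b)
    exact_poisson_rate_test(0, 32.0, b, 38.2, "deficit")$p.value,
    numeric(1)) <= 0.05)
  expect_gte(pow, 0.99)
})
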