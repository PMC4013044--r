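test_that("preference ratio and side bias implement the defining formulas", {
  expect_equal(preference_ratio(0, 500), 0)
  expect_equal(preference_ratio(500, 500), 0.5)
  expect_equal(preference_ratio(509, 491), 0.509)
  expect_true(is.na(preference_ratio(0, 0)))
  expect_error(preference_ratio(-1, 5), "non-negative")

  expect_equal(side_bias(100, 100), 0)
  expect_equal(side_bias(100, 0), -1)
  expect_equal(side_bias(20, 180), 0.8)
  expect_true(is.na(side_bias(0, 0)))

  # complement and antisymmetry properties over random counts
  set.seed(5)
  a <- rpois(200, 40); b <- rpois(200, 60)
  ok <- a + b > 0
  expect_equal(preference_ratio(a, b)[ok] + preference_ratio(b, a)[ok],
               rep(1, sum(ok)))
  expect_equal(side_bias(a, b)[ok], -side_bias(b, a)[ok])
})

test_that("bias classification uses strict +/-0.6 thresholds", {
  x <- c(-0.61, -0.6, 0, 0.6, 0.61, NA)
  got <- classify_bias(x)
  expect_equal(as.character(got),
               c("strong_left", "none", "none", "none", "strong_right", NA))
})

test_that("daily_summary counts time, visits and drinking episodes", {
  tab <- tiny_table()  # visits at t 0, 100, 250 on day 1; one lick-free
  d <- daily_summary(tab)
  expect_equal(nrow(d), 2L)
  a <- d[d$animal_id == "a", ]
  expect_equal(a$visits, 2L)
  expect_equal(a$episodes, 1L)  # second visit of "a" has no licks
  expect_equal(a$time_s, 60)
  expect_equal(d[d$animal_id == "b", ]$time_s, 60)

  expect_equal(nrow(daily_summary(event_table())), 0L)

  # conservation: summing days reproduces whole-table totals
  sched <- build_intermittent(2)
  sim <- simulate_cohort(cohort_config(make_profiles(4), sched, seed = 3))
  d2 <- daily_summary(sim)
  expect_equal(sum(d2$visits), nrow(sim))
  expect_equal(sum(d2$time_s), sum(sim$t_end - sim$t_start))
  expect_equal(sum(d2$episodes),
               sum((sim$licks_left + sim$licks_right) > 0))
})

test_that("circadian_profile bins by preceding hour and conserves counts", {
  # single visit at clock 13.5 h lands in bin 14
  rec <- data.frame(animal_id = "a", corner = 1L, t_start = 13.5 * 3600,
                    t_end = 13.5 * 3600 + 10, nosepokes_left = 0L,
                    nosepokes_right = 0L, licks_left = 0L, licks_right = 0L)
  prof <- circadian_profile(event_table(rec))
  expect_equal(unname(prof["a", 14]), 1)
  expect_equal(sum(prof), 1)

  # an entry exactly on the hour belongs to the preceding bin
  rec$t_start <- 13 * 3600
  expect_equal(unname(circadian_profile(event_table(rec))["a", 13]), 1)

  # empty table -> zero matrix over the roster
  e <- event_table(roster = data.frame(animal_id = c("a", "b")))
  expect_equal(sum(circadian_profile(e)), 0)
  expect_equal(dim(circadian_profile(e)), c(2L, 24L))

  # bins sum to the number of selected-interval events
  sched <- build_intermittent(1)
  sim <- simulate_cohort(cohort_config(make_profiles(3), sched, seed = 9))
  days <- 1:2
  prof2 <- circadian_profile(sim, intervals = days)
  expect_equal(sum(prof2) * length(days),
               sum((floor(sim$t_start / 86400) + 1) %in% days))

  # near-uniform activity gives a flat profile within sampling error:
  # huge peak widths plus a dominating floor make the hourly rate almost
  # constant around the clock
  flat <- mouse_profile("f1", activity = list(
    peak_h = c(6, 18), width_h = c(1e6, 1e6), amplitude = c(5, 5),
    floor_frac = 20))
  sched1 <- build_intermittent(1)
  simf <- simulate_cohort(cohort_config(list(flat), sched1, seed = 4))
  pf <- circadian_profile(simf)
  expect_lt(stats::sd(pf) / mean(pf), 0.25)
})

test_that("duration_distributions matches brute-force enumeration", {
  tab <- tiny_table()
  dd <- duration_distributions(tab)
  expect_equal(sum(dd$durations$counts), 3L)
  # one revisit pair: animal a, corner 1, gap 250 - 30 = 220 s
  expect_equal(dd$revisit_intervals$values, 220)

  # single-visit table: mass 1 duration histogram, empty interval set
  one <- event_table(as.data.frame(tab)[1, ])
  d1 <- duration_distributions(one)
  expect_equal(sum(d1$durations$counts), 1L)
  expect_length(d1$revisit_intervals$values, 0L)

  # simulated table equals brute-force enumeration
  sched <- build_intermittent(1)
  sim <- simulate_cohort(cohort_config(make_profiles(3), sched, seed = 8))
  dd2 <- duration_distributions(sim)
  expect_equal(sort(dd2$durations$values), sort(sim$t_end - sim$t_start))
  brute <- c()
  for (id in roster(sim)$animal_id) {
    for (k in 1:4) {
      v <- sim[sim$animal_id == id & sim$corner == k, , drop = FALSE]
      if (nrow(v) > 1) {
        v <- v[order(v$t_start), ]
        for (i in 2:nrow(v)) brute <- c(brute, v$t_start[i] - v$t_end[i - 1])
      }
    }
  }
  expect_equal(dd2$revisit_intervals$values, sort(brute))

  # simulator respects the stated visit-duration shape
  dur <- sim$t_end - sim$t_start
  expect_gt(mean(dur < 60), 0.5)
  expect_lt(mean(dur > 600), 0.01)
})

test_that("intake and dose conversion reproduces the printed arithmetic", {
  # direct-intake route: 0.436 g at 26 g body weight -> 16.8 g/kg (3 s.f.)
  d <- intake_dose(intake_g = 0.436, weight_g = 26)
  expect_equal(signif(d$dose_g_per_kg, 3), 16.8)

  expect_equal(intake_dose(licks = 0, concentration = 12,
                           weight_g = 26)$intake_g, 0)

  # hand arithmetic: 1000 licks x 3 ul x 12% x 0.789 at 25 g
  d2 <- intake_dose(licks = 1000, concentration = 12, weight_g = 25)
  expect_equal(d2$intake_g, 0.28404)
  expect_equal(d2$dose_g_per_kg, 11.3616)

  # w/v convention omits the density factor
  d3 <- intake_dose(licks = 1000, concentration = 12, weight_g = 25,
                    convention = "w/v")
  expect_equal(d3$intake_g, 0.36)

  expect_error(intake_dose(licks = 10, weight_g = 0), "weight")
})

test_that("BEC estimate scales linearly through the calibration point", {
  expect_equal(estimate_bec(300, 1), 0.1)
  expect_equal(estimate_bec(0, 1), 0)
  expect_equal(estimate_bec(600, 1), 0.2)
  expect_equal(estimate_bec(300, 2), 0.05)
  expect_error(estimate_bec(10, 0), "window")
})

test_that("session_metrics attributes licks by content and bounds ratios", {
  sched <- build_intermittent(2)
  sim <- simulate_cohort(cohort_config(make_profiles(4), sched, seed = 6))
  m <- session_metrics(sim, sched)
  expect_equal(nrow(m), 4 * length(sched))
  expect_true(all(m$preference >= 0 & m$preference <= 1, na.rm = TRUE))
  expect_true(all(abs(m$side_bias) <= 1, na.rm = TRUE))
  # licks by content sum to total licks inside sessions
  insess <- rep(FALSE, nrow(sim))
  for (s in sched) {
    insess <- insess | (sim$t_start >= s$start & sim$t_start < s$end)
  }
  expect_equal(sum(m$licks_alcohol + m$licks_saccharin + m$licks_water),
               sum(sim$licks_left[insess] + sim$licks_right[insess]))
})
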