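# helper: event table of one mouse's visits to a PR session's reward
# corners, given the nose pokes of each visit
pr_fixture <- function(pokes, session, mouse = "a", corner = NULL) {
  rc <- reward_corners(session)
  n <- length(pokes)
  if (is.null(corner)) corner <- rep(rc[1], n)
  t0 <- session$start
  rec <- data.frame(animal_id = mouse, corner = corner,
                    t_start = t0 + seq_len(n) * 100,
                    t_end = t0 + seq_len(n) * 100 + 30,
                    nosepokes_left = as.integer(pokes),
                    nosepokes_right = 0L,
                    licks_left = 0L, licks_right = 0L)
  event_table(rec, roster = data.frame(animal_id = mouse))
}

test_that("pr_criteria builds the arithmetic requirement ladder", {
  expect_equal(pr_criteria(3, 3, 7), c(3L, 6L, 9L, 12L, 15L, 18L, 21L))
  expect_equal(pr_criteria(3, 3, 7)[7], 21L)
  expect_equal(sum(pr_criteria(3, 3, 7)), 84L)  # total responses to 21
  expect_equal(pr_criteria(3, 1, 4), 3:6)
  expect_error(pr_criteria(3, 0, 5), "increment")
  expect_error(pr_criteria(0, 3, 5), "start")
})

test_that("extract_breakpoint walks completions within single visits", {
  ses <- build_pr_sequence("male")[[5]]  # alcohol PR3
  # visits with 3, 6, 9 pokes then nothing -> breakpoint 9
  out <- extract_breakpoint(pr_fixture(c(3, 6, 9, 1, 0), ses), ses, "a")
  expect_equal(out$breakpoint, 9L)
  expect_equal(out$completed, c(3L, 6L, 9L))
  expect_equal(out$post_breakpoint_visits, 2L)

  # no qualifying visit -> breakpoint 0
  out0 <- extract_breakpoint(pr_fixture(c(1, 2, 2), ses), ses, "a")
  expect_equal(out0$breakpoint, 0L)
  expect_equal(out0$post_breakpoint_visits, 3L)

  # two sub-criterion visits between completions are counted
  out2 <- extract_breakpoint(pr_fixture(c(3, 1, 2, 6), ses), ses, "a")
  expect_equal(out2$completed, c(3L, 6L))
  expect_equal(out2$visits_between, c(1L, 3L))

  # pokes beyond the criterion have no consequence: 50 pokes in one visit
  # complete only the current stage
  out3 <- extract_breakpoint(pr_fixture(c(50, 50), ses), ses, "a")
  expect_equal(out3$completed, c(3L, 6L))
  expect_equal(out3$breakpoint, 6L)

  # completed criteria are always a prefix of the ladder (no skipping)
  set.seed(21)
  for (r in 1:20) {
    pokes <- sample(0:12, 15, replace = TRUE)
    o <- extract_breakpoint(pr_fixture(pokes, ses), ses, "a")
    k <- length(o$completed)
    expect_equal(o$completed, pr_criteria(3, 3, max(k, 1))[seq_len(k)])
  }

  expect_error(
    extract_breakpoint(pr_fixture(3, ses), build_intermittent(1)[[1]], "a"),
    "PR")
})

test_that("breakpoint is monotone under appended completions", {
  ses <- build_pr_sequence("male")[[5]]
  base <- c(3, 4, 6)
  o1 <- extract_breakpoint(pr_fixture(base, ses), ses, "a")
  o2 <- extract_breakpoint(pr_fixture(c(base, 9), ses), ses, "a")
  expect_gt(o2$breakpoint, o1$breakpoint)
  # appending non-completions never lowers the breakpoint
  o3 <- extract_breakpoint(pr_fixture(c(base, 0, 1), ses), ses, "a")
  expect_gte(o3$breakpoint, o1$breakpoint)
})

test_that("higher persistence gives stochastically higher breakpoints", {
  ses <- new_sched <- build_pr_sequence("female", reward = "saccharin")
  mk <- function(persistence, id) {
    mouse_profile(id, persistence = persistence,
                  activity = list(peak_h = c(2, 10), width_h = c(2, 2),
                                  amplitude = c(25, 20), floor_frac = 0.05))
  }
  bps <- sapply(1:8, function(r) {
    cfg <- cohort_config(list(mk(6, "low"), mk(30, "high")), new_sched,
                         seed = 100 + r)
    sim <- simulate_cohort(cfg)
    out <- extract_breakpoints(sim, new_sched[[3]])
    c(low = out$breakpoint[out$animal_id == "low"],
      high = out$breakpoint[out$animal_id == "high"])
  })
  expect_gt(mean(bps["high", ]), mean(bps["low", ]))
})

test_that("risk_session_licks splits risk and safe corners", {
  ses <- build_punishment_sequence("male")[[2]]
  rc <- reward_corners(ses)
  safe <- setdiff(1:4, rc)
  rec <- data.frame(
    animal_id = c("a", "a", "b"),
    corner = c(rc[1], safe[1], safe[2]),
    t_start = ses$start + c(100, 200, 300),
    t_end = ses$start + c(130, 230, 330),
    nosepokes_left = 3L, nosepokes_right = 0L,
    licks_left = c(10L, 20L, 7L), licks_right = 0L)
  tab <- event_table(rec, roster = data.frame(animal_id = c("a", "b", "c")))
  out <- risk_session_licks(tab, ses)
  expect_equal(out$licks_risk, c(10L, 0L, 0L))
  expect_equal(out$licks_safe, c(20L, 7L, 0L))

  # all licks on safe corners -> zero risk totals; empty table -> zeros
  empty <- event_table(roster = roster(tab))
  z <- risk_session_licks(empty, ses)
  expect_true(all(z$licks_risk == 0L & z$licks_safe == 0L))

  expect_error(risk_session_licks(tab, build_intermittent(1)[[1]]), "risk")

  # simulated punishment session: totals equal brute-force sums
  sched <- build_punishment_sequence("male")
  sim <- simulate_cohort(cohort_config(make_profiles(4), sched, seed = 13))
  got <- risk_session_licks(sim, sched[[1]])
  s1 <- sched[[1]]
  sub <- sim[sim$t_start >= s1$start & sim$t_start < s1$end, ]
  for (i in seq_len(nrow(got))) {
    v <- sub[sub$animal_id == got$animal_id[i], ]
    expect_equal(got$licks_risk[i],
                 sum(v$licks_left[v$corner %in% reward_corners(s1)]) +
                   sum(v$licks_right[v$corner %in% reward_corners(s1)]))
  }

  # 100% immediate risk suppresses drinking on risk bottles
  expect_lt(sum(got$licks_risk), sum(got$licks_safe) + 1)
})
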