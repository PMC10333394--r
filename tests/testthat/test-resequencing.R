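durations_of <- function(cases) setNames(cases$scheduled_duration, cases$case_id)
los_of <- function(cases) setNames(cases$pacu_los, cases$case_id)

test_that("day reconstruction groups, orders, and flags full days", {
  cases <- make_toy_cases(6, seed = 1)
  cases$surgeon_id <- rep(c("S0001", "S0002"), each = 3)
  days <- reconstruct_or_days(cases)
  expect_length(days, 2)
  expect_equal(days[[1]]$case_ids, cases$case_id[1:3])
  # 400 minutes of content from 07:30 ends 14:10 -> not full
  short <- make_toy_cases(2, seed = 2)
  short$scheduled_duration <- c(250L, 150L)
  short$scheduled_start <- c("07:30", format_hm(450 + 250))
  d <- reconstruct_or_days(short)
  expect_false(d[[1]]$full_day)
  # 480 minutes ends 15:30 -> full
  long <- short
  long$scheduled_duration <- c(250L, 230L)
  expect_true(reconstruct_or_days(long)[[1]]$full_day)
  # boundary: content ending exactly 15:00 counts as full
  exact <- short
  exact$scheduled_duration <- c(250L, 200L)
  expect_true(reconstruct_or_days(exact)[[1]]$full_day)
  # alternative rule: last *start* past the cutoff
  expect_false(reconstruct_or_days(long, rule = "last_start")[[1]]$full_day)
})

test_that("overlapping scheduled cases are reported by id", {
  cases <- make_toy_cases(2, seed = 3)
  cases$scheduled_start <- c("08:00", "08:30")
  cases$scheduled_duration <- c(60L, 60L)
  expect_error(reconstruct_or_days(cases), "T001 overlaps T002")
})

test_that("schedule simulation does sequential clock arithmetic", {
  day <- make_toy_day(2)
  durations <- c(T001 = 60, T002 = 85)
  los <- c(T001 = 81, T002 = 210)
  s <- simulate_schedule(day, day$case_ids, durations, los)
  expect_equal(format_hm(s$pacu_exit), c("09:51", "13:25"))
  expect_equal(format_hm(attr(s, "latest_pacu_exit")), "13:25")
  expect_equal(format_hm(max(s$surgery_end)), "09:55")
  # single case: exit = start + duration + LOS
  d1 <- make_toy_day(1)
  s1 <- simulate_schedule(d1, d1$case_ids, c(T001 = 60), c(T001 = 81))
  expect_equal(s1$pacu_exit, 450 + 60 + 81)
  # reversed order: same latest surgery end (makespan invariance)
  s_rev <- simulate_schedule(day, c("T002", "T001"), durations, los)
  expect_equal(max(s_rev$surgery_end), max(s$surgery_end))
  # turnover shifts downstream starts
  s_t <- simulate_schedule(day, day$case_ids, durations, los, turnover = 15)
  expect_equal(s_t$surgery_start[2], s_t$surgery_end[1] + 15)
  expect_error(simulate_schedule(day, c("T001", "T009"), durations, los),
               "not a permutation")
  expect_error(simulate_schedule(day, day$case_ids, durations, c(T001 = 81)),
               "missing PACU LOS")
})

test_that("risk resequencing sorts descending with stable ties", {
  day <- make_toy_day(3)
  perm <- resequence_by_risk(day, c(T001 = 0.1, T002 = 0.9, T003 = 0.5))
  expect_equal(as.integer(perm), c(2L, 3L, 1L))
  expect_true(attr(perm, "resequenced"))
  # all ties: historic order, not counted as resequenced
  tie <- resequence_by_risk(day, c(T001 = 0.4, T002 = 0.4, T003 = 0.4))
  expect_equal(as.integer(tie), 1:3)
  expect_false(attr(tie, "resequenced"))
  # strictly increasing risks reverse the day
  inc <- resequence_by_risk(day, c(T001 = 0.2, T002 = 0.5, T003 = 0.8))
  expect_equal(as.integer(inc), 3:1)
  # order changes but nothing predicted prolonged -> not "resequenced"
  low <- resequence_by_risk(day, c(T001 = 0.1, T002 = 0.3, T003 = 0.2))
  expect_equal(as.integer(low), c(2L, 3L, 1L))
  expect_false(attr(low, "resequenced"))
  expect_error(resequence_by_risk(day, c(T001 = 0.1, T003 = 0.2)), "T002")
})

test_that("after-hours flag is strict at 19:00", {
  day <- make_toy_day(1)
  mk <- function(exit_min) {
    s <- simulate_schedule(day, day$case_ids, c(T001 = 60),
                           c(T001 = exit_min - 450 - 60))
    s
  }
  expect_true(after_hours_flag(mk(parse_hm("19:01"))))
  expect_false(after_hours_flag(mk(parse_hm("19:00"))))
  expect_false(after_hours_flag(mk(parse_hm("13:25"))))
})

test_that("longest-tail-first attains the exhaustive minimum on every day", {
  # >= 200 synthetic days with 2-7 cases, exhaustive permutation check
  n_checked <- 0L
  withr::with_seed(314, {
    while (n_checked < 200L) {
      k <- sample(2:7, 1)
      day <- make_toy_day(k)
      durations <- setNames(sample(20:150, k, replace = TRUE), day$case_ids)
      los <- setNames(sample(30:260, k, replace = TRUE), day$case_ids)
      bf <- brute_force_min_latest_exit(day, durations, los)
      tail_first <- order(-los[day$case_ids])
      s <- simulate_schedule(day, tail_first, durations, los)
      expect_equal(attr(s, "latest_pacu_exit"), bf$min_latest_exit)
      # makespan invariance across a sampled permutation
      p <- sample(k)
      sp <- simulate_schedule(day, p, durations, los)
      expect_equal(max(sp$surgery_end), max(s$surgery_end))
      n_checked <- n_checked + 1L
    }
  })
  # guard on the factorial search
  big <- make_toy_day(9)
  expect_error(brute_force_min_latest_exit(big, setNames(rep(60, 9), big$case_ids),
                                           setNames(rep(60, 9), big$case_ids)),
               "guarded")
  # two equal-LOS cases: both orderings tie
  d2 <- make_toy_day(2)
  dur2 <- c(T001 = 50, T002 = 90); los2 <- c(T001 = 120, T002 = 120)
  s12 <- simulate_schedule(d2, 1:2, dur2, los2)
  s21 <- simulate_schedule(d2, 2:1, dur2, los2)
  expect_equal(attr(s12, "latest_pacu_exit"), attr(s21, "latest_pacu_exit"))
})

test_that("oracle ordering never worsens a day's after-hours flag", {
  cfg <- cohort_config(n_cases = 1500, seed = 81)
  co <- generate_cohort(cfg)
  days <- reconstruct_or_days(co$cases, full_only = TRUE)
  durations <- durations_of(co$cases); los <- los_of(co$cases)
  worsened <- vapply(days, function(d) {
    hist_f <- after_hours_flag(simulate_schedule(d, d$case_ids, durations, los))
    oracle <- order(-los[d$case_ids])
    orac_f <- after_hours_flag(simulate_schedule(d, oracle, durations, los))
    orac_f > hist_f
  }, logical(1))
  expect_false(any(worsened))
})

test_that("chi-square comparison matches the textbook statistic", {
  # the reference 2x2: 82 vs 24 after-hours days out of 198 per arm
  ht <- after_hours_test(82, 24, 198)
  expect_equal(ht$chi2_stat, chi2_textbook(ht$table), tolerance = 1e-9)
  expect_equal(ht$chi2_stat, 43.34, tolerance = 0.01)
  expect_lt(ht$p_value, 1e-4)
  # random tables against the textbook formula
  withr::with_seed(99, {
    for (i in 1:20) {
      a <- sample(5:50, 1); b <- sample(5:50, 1); n <- 60
      h <- after_hours_test(a, b, n)
      expect_equal(h$chi2_stat, chi2_textbook(h$table), tolerance = 1e-9)
    }
  })
  # identical arms: statistic 0, p = 1
  same <- after_hours_test(10, 10, 30)
  expect_equal(same$chi2_stat, 0)
  expect_equal(same$p_value, 1)
})

test_that("compare_schedules builds a coherent report", {
  cfg <- cohort_config(n_cases = 1200, seed = 91)
  co <- generate_cohort(cfg)
  days <- reconstruct_or_days(co$cases, full_only = TRUE)
  # a well-informed (but imperfect) risk: noisy monotone function of LOS
  risk <- withr::with_seed(17,
    plogis(scale(log(co$cases$pacu_los))[, 1] + rnorm(nrow(co$cases), 0, 0.8)))
  names(risk) <- co$cases$case_id
  rep <- compare_schedules(days, co$cases, risk)
  expect_equal(unname(rowSums(rep$table_2x2)), rep(rep$n_days, 2))
  expect_gte(rep$chi2_stat, 0)
  expect_true(rep$p_value >= 0 && rep$p_value <= 1)
  expect_equal(rep$n_days, length(days))
  expect_lte(sum(rep$per_day$resequenced_after_hours),
             sum(rep$per_day$historic_after_hours))
  expect_error(compare_schedules(list(), co$cases, risk), "no full OR days")
})
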