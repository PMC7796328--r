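test_that("constant input gives constant bin medians", {
  ev <- window_events(rep(500, 300), 0, 30)
  tr <- bin_median_trace(ev, "fl1_a", 2)
  expect_true(all(tr$median[tr$valid] == 500))
})

test_that("bin medians match a brute-force per-bin median", {
  # two-point bin
  ev <- window_events(c(100, 300), 0, 2)
  tr <- bin_median_trace(ev, "fl1_a", 2, min_events = 1)
  expect_equal(tr$median[1], 200)
  # random instance vs split + median oracle, permutation invariance
  set.seed(41)
  n <- 5000
  t <- runif(n, 0, 60)
  x <- rlnorm(n, 8, 0.5)
  ev2 <- window_events(x[order(t)], 0, 60)
  ev2$time_s <- sort(t)
  tr2 <- bin_median_trace(ev2, "fl1_a", 5, duration_s = 60, min_events = 1)
  oracle <- vapply(split(ev2$fl1_a, floor(ev2$time_s / 5)), median,
                   numeric(1))
  expect_equal(unname(tr2$median), unname(oracle))
})

test_that("empty bins are flagged and excluded", {
  ev <- window_events(rep(500, 100), 0, 10)   # nothing after 10 s
  tr <- bin_median_trace(ev, "fl1_a", 2, duration_s = 20)
  expect_false(any(tr$valid[tr$time_s > 10]))
  expect_true(all(is.na(tr$median[tr$n == 0])))
  expect_error(bin_median_trace(ev, "fl9_a", 2), "channel")
})

test_that("plateau windows follow the settle/width arithmetic", {
  sched <- stimulus_schedule(time_s = c(120, 240, 360), compound = rep("KCl", 3),
                             amount = c(10, 15, 25), unit = rep("mM", 3),
                             duration_s = 480)
  w <- plateau_windows(sched, settle_s = 90, width_s = 30)
  expect_equal(w$start_s, c(210, 330, 450))
  expect_equal(w$end_s, c(240, 360, 480))
  # each window ends exactly at the next addition
  expect_equal(w$end_s[-3], sched$time_s[-1])
  expect_error(plateau_windows(sched, settle_s = 110, width_s = 30),
               "overlap")
})

test_that("plateau median isolates the responding subpopulation", {
  set.seed(42)
  n <- 5000
  resp <- runif(n) < 0.8
  x <- ifelse(resp, 10^rnorm(n, 4, 0.12), 10^rnorm(n, 3, 0.12))
  ev <- window_events(x, 0, 30)
  m_resp <- plateau_median(ev, "fl1_a", c(0, 30), subpop = "responding",
                           direction = "high")
  oracle <- median(x[resp])
  expect_lt(abs(m_resp - oracle) / oracle, 0.05)
  # unimodal window: responding equals all
  ev_uni <- window_events(10^rnorm(n, 4, 0.12), 0, 30)
  expect_equal(as.numeric(plateau_median(ev_uni, "fl1_a", c(0, 30),
                                         subpop = "responding")),
               as.numeric(plateau_median(ev_uni, "fl1_a", c(0, 30),
                                         subpop = "all")))
})

test_that("plateau median refuses thin windows", {
  ev <- window_events(rep(100, 10), 0, 30)
  expect_error(plateau_median(ev, "fl1_a", c(0, 30), min_events = 200),
               "10 events")
})

test_that("normalization maps baseline to zero and scales fractionally", {
  ev <- window_events(rep(100, 4000), 0, 200)
  tr <- bin_median_trace(ev, "fl1_a", 2, min_events = 1)
  tr$median[tr$time_s > 120] <- c(290, rep(100, sum(tr$time_s > 120) - 2), 50)
  norm <- normalize_trace(tr, c(0, 120))
  expect_equal(attr(norm, "F0"), 100)
  expect_true(all(norm$median[norm$time_s < 120] == 0))
  expect_equal(max(norm$median), 1.90)
  expect_equal(min(norm$median), -0.5)
})

test_that("normalization is invariant to raw intensity scaling", {
  set.seed(43)
  x <- rlnorm(6000, log(1e4), 0.2) * (1 + 0.5 * (seq_len(6000) > 3000))
  ev1 <- window_events(x, 0, 300)
  ev2 <- window_events(7.3 * x, 0, 300)
  n1 <- normalize_trace(bin_median_trace(ev1, "fl1_a", 2), c(0, 120))
  n2 <- normalize_trace(bin_median_trace(ev2, "fl1_a", 2), c(0, 120))
  expect_equal(n1$median, n2$median, tolerance = 1e-12)
  expect_error(normalize_trace(bin_median_trace(
    window_events(rep(0, 4000), 0, 130), "fl1_a", 2), c(0, 120)),
    "positive")
})

test_that("schedule invariants are enforced", {
  expect_error(stimulus_schedule(c(120, 120), c("a", "b"), c(1, 2),
                                 c("mM", "mM"), 400), "increasing")
  expect_error(stimulus_schedule(c(60), "a", 1, "mM", 400), "baseline")
  expect_error(stimulus_schedule(c(500), "a", 1, "mM", 400), "within")
  # shipped protocol schedules are internally consistent
  for (s in list(em_schedule(), ca_schedule(), ph_htf_schedule(),
                 ph_cal_schedule()))
    expect_s3_class(s, "stimulus_schedule")
  expect_equal(nrow(ph_cal_schedule()), 8)   # 0.25-unit KOH ladder to 8.0
})
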