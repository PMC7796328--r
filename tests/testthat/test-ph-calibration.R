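test_that("Henderson-Hasselbalch base fraction has the titration symmetries", {
  expect_equal(hh_base_fraction(7.55), 0.5)
  expect_equal(hh_base_fraction(6.0), 0.02741, tolerance = 1e-4)
  expect_equal(hh_base_fraction(1e6), 1)
  # monotone and reflection-symmetric about the pKa
  ph <- seq(5, 10, by = 0.1)
  expect_true(all(diff(hh_base_fraction(ph)) > 0))
  for (d in c(0.3, 1, 2.5))
    expect_equal(hh_base_fraction(7.55 + d) + hh_base_fraction(7.55 - d), 1)
})

test_that("KOH amounts follow the buffer titration closed form", {
  expect_equal(as.numeric(koh_addition_amount(25, 1, 6.5, 6.5)), 0)
  # 25 mM HEPES, 1 mL, 6.00 -> 6.25
  step <- koh_addition_amount(25, 1, 6.00, 6.25)
  expect_equal(as.numeric(step), 0.508, tolerance = 1e-3)
  expect_error(koh_addition_amount(25, 1, 6.5, 6.0), "pH_to")
  # stock volume attachment
  with_stock <- koh_addition_amount(25, 1, 6.0, 6.25, stock_mM = 100)
  expect_equal(attr(with_stock, "stock_volume_uL"),
               as.numeric(with_stock) / 100 * 1000)
})

test_that("the 6.0 -> 8.0 ladder telescopes to the closed-form total", {
  sched <- koh_schedule(buffer_mM = 25, volume_mL = 1)
  expect_equal(nrow(sched), 8)
  total <- 25 * 1 * (hh_base_fraction(8.0) - hh_base_fraction(6.0))
  expect_equal(sum(sched$koh_umol), total, tolerance = 1e-12)
})

test_that("pH calibration fit recovers an exact generating log-line", {
  ph <- seq(6.0, 8.0, by = 0.25)
  f <- 10^(-0.29 * ph - 1.93)
  fit <- fit_ph_calibration(ph, f)
  expect_equal(fit$slope, -0.29)
  expect_equal(fit$intercept, -1.93)
  expect_equal(fit$r_squared, 1)
  expect_error(fit_ph_calibration(ph[1:3], f[1:3]), "4 distinct")
  f_bad <- f; f_bad[3] <- 0
  expect_error(fit_ph_calibration(ph, f_bad), "positive")
})

test_that("noisy pH fit matches the normal-equations oracle", {
  set.seed(61)
  for (i in 1:20) {
    ph <- seq(6, 8, length.out = 9)
    logf <- 0.3 * ph + 1.5 + rnorm(9, 0, 0.02)
    fit <- fit_ph_calibration(ph, 10^logf, r2_min = 0)
    X <- cbind(1, ph)
    beta <- solve(t(X) %*% X, t(X) %*% logf)
    expect_equal(fit$intercept, beta[1], tolerance = 1e-9)
    expect_equal(fit$slope, beta[2], tolerance = 1e-9)
  }
})

test_that("pH interpolation inverts the calibration", {
  ph <- seq(6.0, 8.0, by = 0.25)
  fit <- fit_ph_calibration(ph, 10^(-0.29 * ph - 1.93))
  expect_equal(interpolate_ph(fit, 10^(-3.8904)), 6.76, tolerance = 1e-3)
  for (x in c(6.2, 7.0, 7.8))
    expect_equal(interpolate_ph(fit, 10^(-0.29 * x - 1.93)), x)
  expect_warning(interpolate_ph(fit, 10^(-0.29 * 9 - 1.93)), "extrapolat")
  expect_error(interpolate_ph(fit, -1), "positive")
})

test_that("titration points self-interpolate within 0.05 pH at high R2", {
  set.seed(62)
  ph <- seq(6.0, 8.0, by = 0.25)
  f <- 10^(0.3 * ph + 1.5 + rnorm(9, 0, 0.005))
  fit <- fit_ph_calibration(ph, f)
  expect_gte(fit$r_squared, 0.99)
  back <- vapply(f, function(x) interpolate_ph(fit, x), numeric(1))
  expect_true(all(abs(back - ph) <= 0.05))
})

test_that("delta-pH classification follows the 0.1-unit band", {
  expect_equal(as.character(classify_delta_ph(6.58, 6.94)), "alkalinized")
  expect_equal(attr(classify_delta_ph(6.58, 6.94), "delta"), 0.36)
  expect_equal(as.character(classify_delta_ph(7.0, 7.0)), "unchanged")
  expect_equal(as.character(classify_delta_ph(7.0, 6.85)), "acidified")
  expect_equal(as.character(classify_delta_ph(7.0, 7.1)), "unchanged")
})

test_that("NH4Cl control detects alkalinization and rejects flat traces", {
  cfg <- quick_cfg(seed = 63)
  sim <- simulate_ph_run(cfg, 6.76)
  g_htf <- gate_events(sim$htf)
  g_cal <- gate_events(sim$cal)
  sc <- ph_cal_schedule()
  wins <- plateau_windows(sc)
  med <- vapply(seq_len(nrow(wins)), function(i)
    as.numeric(plateau_median(g_cal, "fl1_a", wins[i, ])), numeric(1))
  f60 <- as.numeric(plateau_median(g_cal, "fl1_a", c(90, 120)))
  fit <- fit_ph_calibration(c(6.0, sc$amount), c(f60, med))
  trace <- bin_median_trace(g_htf, "fl1_a", 2, 300)
  ctrl <- nh4cl_responsiveness(trace, ph_htf_schedule(), fit)
  expect_true(ctrl$pass)
  expect_equal(ctrl$magnitude, 0.56, tolerance = 0.05)
  expect_equal(ctrl$baseline_ph, 6.76, tolerance = 0.05)
  # flat trace: reuse the calibration but a stimulus-free recording
  flat <- window_events(rep(2500, 6000), 0, 300)
  flat_tr <- bin_median_trace(flat, "fl1_a", 2, 300)
  ctrl2 <- nh4cl_responsiveness(flat_tr, ph_htf_schedule(), fit)
  expect_false(ctrl2$pass)
  expect_equal(ctrl2$magnitude, 0, tolerance = 1e-9)
  # boundary: a rise exactly at the pass floor fails (strict inequality)
  step_tr <- flat_tr
  step_tr$median[step_tr$time_s >= 120] <- 2500 * 10^(fit$slope * 0.1)
  ctrl3 <- nh4cl_responsiveness(step_tr, ph_htf_schedule(), fit)
  expect_equal(ctrl3$magnitude, 0.1, tolerance = 1e-9)
  at_floor <- nh4cl_responsiveness(step_tr, ph_htf_schedule(), fit,
                                   min_rise = ctrl3$magnitude)
  expect_false(at_floor$pass)
  sched_bad <- stimulus_schedule(150, "KOH", 1, "mM", 300)
  expect_error(nh4cl_responsiveness(flat_tr, sched_bad, fit), "NH4Cl")
})
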