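test_that("zero thresholds are a no-op debris gate", {
  ev <- toy_events(50)
  out <- apply_debris_gate(ev, gate_config(fsc_min = 0, ssc_min = 0))
  expect_equal(as.data.frame(out), as.data.frame(ev), ignore_attr = TRUE)
  expect_equal(attr(out, "retained_fraction"), 1)
})

test_that("debris gate removes exactly the labeled debris events", {
  set.seed(11)
  cells <- event_table(time_s = sort(runif(100, 0, 10)),
                       fsc_a = rlnorm(100, log(2e5), 0.1),
                       fsc_h = rlnorm(100, log(1.8e5), 0.1),
                       ssc_a = rlnorm(100, log(8e4), 0.1),
                       fl1_a = rep(1e4, 100), fl4_a = rep(1e5, 100),
                       label = rep("viable", 100))
  debris <- event_table(time_s = sort(runif(50, 0, 10)),
                        fsc_a = runif(50, 10, 1e4),
                        fsc_h = runif(50, 10, 1e4),
                        ssc_a = runif(50, 10, 1e4),
                        fl1_a = rep(30, 50), fl4_a = rep(100, 50),
                        label = rep("debris", 50))
  both <- rbind(as.data.frame(cells), as.data.frame(debris))
  mix <- as_event_table(both[order(both$time_s), ])
  out <- apply_debris_gate(mix, gate_config(fsc_min = 5e4, ssc_min = 2e4))
  expect_equal(nrow(out), 100)
  expect_true(all(out$label == "viable"))
})

test_that("gating everything out returns a warned empty table", {
  ev <- toy_events(10)
  expect_warning(out <- apply_debris_gate(ev, gate_config(fsc_min = 1e9)),
                 "removed every event")
  expect_equal(nrow(out), 0)
})

test_that("singlet gate removes simulated doublets by pulse geometry", {
  set.seed(21)
  n <- 2000
  single <- rlnorm(n, log(2e5), 0.15)
  ratio <- rnorm(n, 0.9, 0.03)
  dbl <- runif(n) < 0.1
  fsc_a <- ifelse(dbl, 2 * single, single)
  fsc_h <- ifelse(dbl, 1.2 * single * ratio, single * ratio)
  ev <- event_table(time_s = seq(0, 10, length.out = n), fsc_a = fsc_a,
                    fsc_h = fsc_h, ssc_a = rep(8e4, n),
                    fl1_a = rep(1e4, n), fl4_a = rep(1e5, n),
                    label = ifelse(dbl, "doublet", "viable"))
  out <- apply_singlet_gate(ev, gate_config(singlet_band = c(0.75, 1.05)))
  removed_doublets <- sum(dbl) - sum(out$label == "doublet")
  expect_gte(removed_doublets / sum(dbl), 0.99)
  expect_gte(sum(out$label == "viable") / sum(!dbl), 0.99)
})

test_that("mid-band ratios and an unbounded band pass unchanged", {
  ev <- toy_events(20)
  ev$fsc_h <- 0.9 * ev$fsc_a
  out <- apply_singlet_gate(ev, gate_config(singlet_band = c(0.75, 1.05)))
  expect_equal(nrow(out), 20)
  out2 <- apply_singlet_gate(ev, gate_config(singlet_band = c(0, Inf)))
  expect_equal(as.data.frame(out2)[1:6], as.data.frame(ev)[1:6])
})

test_that("valley threshold lands between killed and viable modes", {
  set.seed(31)
  killed <- window_events(10^rnorm(3000, 2, 0.2))
  stained <- window_events(10^rnorm(3000, 4, 0.2))
  thr <- auto_viability_threshold(stained, killed)
  expect_gt(thr, 1e2)
  expect_lt(thr, 1e4)
})

test_that("inseparable distributions are refused", {
  set.seed(32)
  x <- 10^rnorm(3000, 3, 0.2)
  expect_error(auto_viability_threshold(window_events(x), window_events(x)),
               "not separable")
})

test_that("zero-overlap samples give a threshold inside the gap", {
  set.seed(33)
  killed <- window_events(runif(1000, 50, 100))
  stained <- window_events(runif(1000, 1e4, 2e4))
  thr <- auto_viability_threshold(stained, killed)
  expect_gt(thr, 100)
  expect_lt(thr, 1e4)
})

test_that("gates are subsetting filters and the chain is idempotent", {
  cfg <- quick_cfg(seed = 5)
  sim <- simulate_em_run(cfg, -65)
  g <- gate_events(sim$events)
  expect_lte(nrow(g), nrow(sim$events))
  # re-applying with the realized numeric threshold changes nothing
  fixed <- gate_config(viability = attr(g, "viability_threshold"))
  g2 <- gate_events(g, fixed)
  expect_equal(as.data.frame(g2), as.data.frame(g), ignore_attr = TRUE)
})

test_that("viable-singlet recall and precision exceed 0.95 on labeled data", {
  cfg <- quick_cfg(seed = 6)
  sim <- simulate_em_run(cfg, -60)
  g <- gate_events(sim$events)
  truth_pos <- sim$events$label == "viable"
  kept_pos <- g$label == "viable"
  recall <- sum(kept_pos) / sum(truth_pos)
  precision <- mean(kept_pos)
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
})
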