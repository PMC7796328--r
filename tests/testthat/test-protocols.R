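test_that("Em protocol classifies a simulated hyperpolarizing pair", {
  cfg <- quick_cfg(seed = 101)
  nc <- simulate_em_run(cfg, -60, seed = 101)
  cap <- simulate_em_run(cfg, -71, seed = 102)
  res <- run_protocol("em", list(nc = nc$events, cap = cap$events),
                      sample_id = "s1", donor_class = "known_paternity")
  expect_s3_class(res, "sample_result")
  expect_equal(res$parameter, "Em")
  expect_equal(res$nc, -60, tolerance = 1)
  expect_equal(res$cap, -71, tolerance = 1)
  expect_equal(res$category, "hyperpolarized")
  expect_equal(res$status, "ok")
  expect_gte(min(res$qc$r2_nc, res$qc$r2_cap), 0.99)
})

test_that("pH protocol needs its calibration aliquots", {
  cfg <- quick_cfg(seed = 103)
  sim <- simulate_ph_run(cfg, 6.76)
  expect_error(run_protocol("ph", list(nc = sim$htf, cap = sim$htf,
                                       cal_nc = sim$cal)),
               "cal_cap")
})

test_that("equal calcium peaks classify as unchanged", {
  cfg <- quick_cfg(seed = 104)
  sim <- simulate_ca_run(cfg, 1.2, 1.2)
  res <- run_protocol("ca", list(nc = sim$nc, cap = sim$cap))
  expect_equal(res$category, "unchanged")
  expect_true(res$qc$dynamic_range_nc)
})

test_that("results serialize and re-load through JSON", {
  cfg <- quick_cfg(seed = 105)
  sim <- simulate_ca_run(cfg, 0.5, 1.5)
  res <- run_protocol("ca", list(nc = sim$nc, cap = sim$cap),
                      sample_id = "s9", donor_class = "known_paternity")
  tf <- withr::local_tempfile(fileext = ".json")
  write_sample_result(res, tf)
  back <- read_sample_result(tf)
  expect_equal(back$sample_id, "s9")
  expect_equal(back$delta, res$delta)
  expect_equal(back$category, res$category)
})

fake_result <- function(id, nc, cap, category, parameter = "pHi",
                        donor_class = "known_paternity") {
  structure(list(sample_id = id, donor_class = donor_class,
                 parameter = parameter, nc = nc, cap = cap,
                 delta = cap - nc, category = category,
                 qc = list(), status = "ok", flags = character(0)),
            class = "sample_result")
}

test_that("cohort summary reproduces the 8/8 -> 100% wording", {
  set.seed(106)
  results <- lapply(1:8, function(i)
    fake_result(paste0("s", i), 6.58 + rnorm(1, 0, 0.05),
                6.94 + rnorm(1, 0, 0.05), "alkalinized"))
  rep_ <- run_cohort(results)
  s <- rep_$classes$known_paternity$summary
  expect_equal(s$count[s$category == "alkalinized"], 8)
  expect_equal(s$percent[s$category == "alkalinized"], 100)
  expect_equal(rep_$classes$known_paternity$paired$n, 8)
  tab <- cohort_table(rep_)
  expect_named(tab, c("donor_class", "parameter", "category", "count",
                      "percent"))
})

test_that("cohort refuses small or mixed-parameter inputs", {
  r1 <- fake_result("a", 6.5, 6.9, "alkalinized")
  r2 <- fake_result("b", 6.5, 6.9, "alkalinized")
  expect_error(run_cohort(list(r1, r2)), "fewer than 3")
  r3 <- fake_result("c", 6.5, 6.9, "alkalinized")
  r4 <- fake_result("d", -60, -70, "hyperpolarized", parameter = "Em")
  expect_error(run_cohort(list(r1, r2, r3, r4)), "mixed parameters")
})

test_that("rerunning a protocol on identical inputs is reproducible", {
  cfg <- quick_cfg(seed = 107)
  sim <- simulate_ca_run(cfg, 0.8, 1.6)
  r1 <- run_protocol("ca", list(nc = sim$nc, cap = sim$cap))
  r2 <- run_protocol("ca", list(nc = sim$nc, cap = sim$cap))
  expect_equal(r1[c("nc", "cap", "delta", "category", "qc")],
               r2[c("nc", "cap", "delta", "category", "qc")])
})

test_that("command-line entry round-trips simulate -> analyze -> cohort", {
  out <- withr::local_tempdir()
  expect_equal(tlfc_main(c("simulate", "ca", "--seed", "5", "--out", out)),
               0L)
  expect_true(file.exists(file.path(out, "ca_nc.fcs")))
  res_json <- file.path(out, "r1.json")
  code <- tlfc_main(c("ca", "--nc", file.path(out, "ca_nc.fcs"),
                      "--cap", file.path(out, "ca_cap.fcs"),
                      "--sample", "s1", "--donor-class", "known_paternity",
                      "--out", res_json))
  expect_equal(code, 0L)
  expect_true(file.exists(res_json))
  expect_equal(tlfc_main(c("inspect", file.path(out, "ca_nc.fcs"))), 0L)
  # unknown inputs exit with the input-error code
  expect_equal(tlfc_main(c("ca", "--nc", "missing.fcs")), 4L)
})
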