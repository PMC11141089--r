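test_that("steady-state pupil model is monotone and bounded", {
  d <- pupil_steady_state(c(0.1, 1, 10, 100, 1000))
  expect_true(all(diff(d) < 0))
  expect_true(all(d > 2 & d < 7))
  expect_error(pupil_steady_state(0), class = "melanophot_validation_error")
  expect_error(pupil_steady_state(10, d_max_mm = 2, d_min_mm = 3),
               class = "melanophot_validation_error")
})

test_that("noiseless traces are exactly the steady-state diameter", {
  quiet <- list(ar_sd_mm = 0, blink_rate_hz = 0, low_conf_frac = 0)
  tr <- simulate_pupil_trace(50, duration_s = 10, rate_hz = 20,
                             pupil = quiet, seed = 4)
  expect_equal(unique(tr$samples$diameter_mm), pupil_steady_state(50))
  # monotone in dose
  lo <- simulate_pupil_trace(5, 10, 20, pupil = quiet, seed = 4)
  hi <- simulate_pupil_trace(120, 10, 20, pupil = quiet, seed = 4)
  expect_gt(mean(lo$samples$diameter_mm), mean(hi$samples$diameter_mm))
})

test_that("traces are deterministic under a seed", {
  a <- simulate_pupil_trace(30, 5, 50, seed = 99)
  b <- simulate_pupil_trace(30, 5, 50, seed = 99)
  expect_identical(a, b)
})

test_that("heavy blink contamination is removed by the pipeline", {
  # ~30% of samples blink-contaminated at 20 min x 200 Hz
  tr <- simulate_pupil_trace(40, duration_s = 1200, rate_hz = 200,
                             pupil = list(blink_rate_hz = 1,
                                          blink_duration_s = 0.3),
                             seed = 12)
  raw_frac <- mean(tr$samples$diameter_mm < 2 | tr$samples$confidence < 0.6)
  expect_gt(raw_frac, 0.2)
  b <- bin_median(filter_samples(tr), bin_minutes = 20)
  expect_lt(abs(b$median_diameter_mm - pupil_steady_state(40)), 0.05)
})

test_that("suppression factor has its defining limits", {
  expect_equal(suppression_factor(1e-9, 30), 1, tolerance = 1e-9)
  expect_equal(suppression_factor(30, 30), 0.5)
  expect_equal(suppression_factor(600, 600, hill = 2), 0.5)
  expect_true(all(diff(suppression_factor(c(1, 10, 100, 1000), 30)) < 0))
  expect_error(suppression_factor(-1, 30),
               class = "melanophot_validation_error")
})

test_that("noiseless melatonin AUC matches the analytic integral", {
  m <- list(noise_sd_log = 0, peak_pg_ml = 20, rise_midpoint_h = -2,
            rise_rate = 2, s50_corneal = 30, hill = 1,
            exposure_h = c(-4, -0.5))
  prof <- simulate_melatonin_profile(30, melatonin = m, seed = 1)
  auc <- melatonin_auc(prof$time_h, prof$conc_pg_ml, window = c(-4, -0.5))
  # integral of peak * s * plogis((t - t0) k) over the window, s = 0.5
  k <- 2; t0 <- -2
  anti <- function(t) log(1 + exp(k * (t - t0))) / k
  exact <- 20 * 0.5 * (anti(-0.5) - anti(-4))
  expect_lt(abs(auc - exact) / exact, 0.005)  # within the trapezoid bound
  expect_true(all(prof$conc_pg_ml >= 0))
})

test_that("generate_study produces the full counterbalanced design", {
  cfg <- sim_config(n_per_group = 2, seed = 7,
                    pupil = list(n_parts = 2, part_minutes = 1, rate_hz = 5))
  st <- generate_study(cfg)
  expect_equal(nrow(st$sessions), 16L)             # 8 subjects x 2 sessions
  expect_length(st$recordings, 32L)                # x 2 parts
  expect_equal(sort(unique(st$sessions$group)), 1:4)
  # counterbalancing: half of each group sees LM first
  first <- st$sessions[st$sessions$visit == 1L, ]
  tab <- table(first$group, first$arm)
  expect_true(all(tab == 1L))
  # generated samples respect type invariants
  conf <- unlist(lapply(st$recordings, function(r) r$samples$confidence))
  expect_true(all(conf >= 0 & conf <= 1))
  expect_true(all(st$melatonin$conc_pg_ml >= 0))
  # byte-identical reruns under the same seed
  st2 <- generate_study(cfg)
  expect_identical(st, st2)
})

test_that("written study bundles re-enter the pipeline", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_per_group = 1, seed = 3,
                    pupil = list(n_parts = 1, part_minutes = 1, rate_hz = 5))
  st <- generate_study(cfg)
  write_study(st, dir)
  expect_true(file.exists(file.path(dir, "pupil.csv")))
  recs <- read_pupil_csv(file.path(dir, "pupil.csv"), expected_rate_hz = 5)
  expect_length(recs, length(st$recordings))
  expect_true(file.exists(file.path(dir, "melatonin.csv")))
  expect_true(file.exists(file.path(dir, "conditions.csv")))
})

test_that("retinal-dose mechanism is detectable when pupils vary independently", {
  # when suppression truly depends on retinal dose and pupil size varies
  # strongly between subjects, the troland predictor must win in >= 90%
  # of replicates
  wins <- 0L
  n_rep <- 30L
  for (i in seq_len(n_rep)) {
    cfg <- sim_config(seed = 1000 + i,
                      pupil = list(subject_sd_mm = 1.2),
                      melatonin = list(suppression_driver = "retinal"))
    sess <- process_study(generate_study(cfg, pupil_traces = FALSE))$sessions
    cmp <- compare_predictors(sess$auc, sess$medi_lx, sess$mel_td)
    wins <- wins + (cmp$delta_abs_r > 0)
  }
  expect_gte(wins, ceiling(0.9 * n_rep))
})

test_that("dose-driven pupils make corneal and retinal predictors equivalent", {
  deltas <- vapply(1:15, function(i) {
    cfg <- sim_config(seed = 2000 + i, pupil = list(subject_sd_mm = 0.1))
    sess <- process_study(generate_study(cfg, pupil_traces = FALSE))$sessions
    abs(compare_predictors(sess$auc, sess$medi_lx, sess$mel_td)$delta_abs_r)
  }, numeric(1L))
  expect_lt(median(deltas), 0.05)
})

test_that("the recovery harness identifies e50 given the diameter range", {
  cfg <- sim_config(seed = 31)
  sess <- process_study(generate_study(cfg, pupil_traces = FALSE))$sessions
  rec <- recover_pupil_model(sess$medi_lx, sess$median_diameter_mm,
                             d_range = c(2, 7))
  expect_lt(abs(rec$coef[["e50_lx"]] / 20 - 1), 0.25)
  expect_lt(abs(rec$coef[["hill"]] / 0.5 - 1), 0.5)
})
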