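rec_from <- function(d, conf, rate = 200) {
  n <- length(d)
  pupil_recording((seq_len(n) - 1) / rate, d, conf,
                  expected_rate_hz = rate, duration_s = n / rate)
}

test_that("sample filtering applies the three clauses at their boundaries", {
  d <- c(5.0, 1.99, 2.0, 10.0, 10.01, 5.0)
  conf <- c(0.59, 0.90, 0.60, 0.80, 0.90, 0.61)
  out <- filter_samples(rec_from(d, conf))
  # removed: conf 0.59; d 1.99; d 10.01. kept: boundaries 0.6, 2.0, 10.0
  expect_equal(out$samples$diameter_mm, c(2.0, 10.0, 5.0))
  expect_equal(out$samples$confidence, c(0.60, 0.80, 0.61))
  # idempotent
  expect_equal(filter_samples(out)$samples, out$samples)
  # empty in, empty out
  empty <- filter_samples(rec_from(numeric(0), numeric(0)))
  expect_equal(nrow(empty$samples), 0L)
})

test_that("binning takes medians of surviving samples per bin", {
  rec <- rec_from(c(3, 4, 100, 5), rep(1, 4), rate = 1)
  b <- bin_median(filter_samples(rec), bin_minutes = 1)
  expect_equal(b$median_diameter_mm, 4)  # 100 mm filtered out
  expect_equal(b$n_valid, 3L)

  # even count: mean of the two central values
  b2 <- bin_median(filter_samples(rec_from(c(3, 5), c(1, 1), rate = 1)),
                   bin_minutes = 1)
  expect_equal(b2$median_diameter_mm, 4)

  # constant diameter
  b3 <- bin_median(filter_samples(rec_from(rep(4.2, 50), rep(1, 50))),
                   bin_minutes = 20)
  expect_equal(b3$median_diameter_mm, 4.2)

  # order invariance within a bin
  set.seed(1)
  d <- runif(100, 3, 6)
  r1 <- bin_median(rec_from(d, rep(1, 100)), 20)
  r2 <- bin_median(rec_from(sort(d), rep(1, 100)), 20)
  expect_equal(r1$median_diameter_mm, r2$median_diameter_mm)

  # zero valid samples: excluded flag, no median
  b0 <- bin_median(filter_samples(rec_from(c(1, 1), c(1, 1), rate = 1)),
                   bin_minutes = 1)
  expect_true(b0$excluded)
  expect_true(is.na(b0$median_diameter_mm))
})

test_that("quality exclusion uses a strict 2% threshold", {
  mk <- function(frac) data.frame(
    subject = "S01", session = "LM", part = "P1", bin = 1L,
    median_diameter_mm = 5, n_valid = 100L, fraction_valid = frac,
    excluded = FALSE, reason = "")
  bins <- rbind(mk(0.019), mk(0.02), mk(0.5))
  out <- exclude_low_quality(bins)
  expect_equal(out$excluded, c(TRUE, FALSE, FALSE))
  expect_equal(out$reason[1], "low_quality")
  expect_equal(nrow(attr(out, "exclusion_log")), 1L)
  # all parts above threshold: identity
  ok <- rbind(mk(0.5), mk(0.9))
  expect_equal(exclude_low_quality(ok)$excluded, c(FALSE, FALSE))
})

test_that("fraction_valid counts against expected samples, not recorded ones", {
  # 1 minute nominal at 200 Hz with only 120 recorded valid samples -> 1%
  rec <- pupil_recording((0:119) / 2, rep(5, 120), rep(1, 120),
                         expected_rate_hz = 200, duration_s = 60)
  b <- bin_median(filter_samples(rec), bin_minutes = 1)
  expect_equal(b$fraction_valid, 120 / (60 * 200))
  out <- exclude_low_quality(b)
  expect_true(out$excluded)  # storage dropout counts against quality
})

test_that("pupil geometry helpers are exact", {
  expect_equal(diameter_to_area(2), pi)
  expect_equal(diameter_to_area(5), pi * 2.5^2)
  d <- seq(2, 8, 0.5)
  expect_true(all(diff(diameter_to_area(d)) > 0))
  expect_error(diameter_to_area(0), class = "melanophot_validation_error")
  expect_equal(relative_increase(6, 5), 20)
  expect_equal(relative_increase(4.4, 4.4), 0)
  expect_error(relative_increase(5, 0), class = "melanophot_validation_error")
})

test_that("eye-tracker CSV import splits by subject/session/part", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(timestamp_s = rep(0:4 / 10, 2),
                   diameter_3d_mm = rep(5, 10), confidence = rep(1, 10),
                   subject = "S01", session = rep(c("LM", "HM"), each = 5),
                   part = "P1")
  write.csv(df, path, row.names = FALSE)
  recs <- read_pupil_csv(path)
  expect_length(recs, 2L)
  expect_setequal(vapply(recs, `[[`, "", "session"), c("LM", "HM"))
})
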