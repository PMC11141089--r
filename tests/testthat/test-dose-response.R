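test_that("melatonin AUC integrates profiles exactly for simple shapes", {
  # constant 10 pg/ml over 3.5 h
  t <- seq(-4, -0.5, 0.5)
  expect_equal(melatonin_auc(t, rep(10, length(t))), 35)
  # triangle: linear 0 -> 10 over 2 h
  expect_equal(melatonin_auc(c(0, 2), c(0, 10)), 10)
  # quadratic against the closed-form integral, within the trapezoid bound
  tt <- seq(0, 4, 0.5)
  f <- function(x) 3 + 2 * x + x^2
  exact <- 3 * 4 + 4^2 + 4^3 / 3
  err_bound <- 0.5^2 / 12 * 2 * 4   # h^2/12 * max|f''| * range
  expect_lt(abs(melatonin_auc(tt, f(tt)) - exact), err_bound + 1e-12)
  expect_error(melatonin_auc(c(0, 1), c(1, 1), window = c(0.4, 0.45)),
               class = "melanophot_insufficient_data_error")
  expect_error(melatonin_auc(c(0, 0), c(1, 1)),
               class = "melanophot_validation_error")
})

test_that("AUC is additive over adjacent windows", {
  set.seed(8)
  t <- seq(-5, 0, 0.5)
  y <- runif(length(t), 0, 30)
  whole <- melatonin_auc(t, y, window = c(-4, -0.5))
  parts <- melatonin_auc(t, y, window = c(-4, -2.25)) +
    melatonin_auc(t, y, window = c(-2.25, -0.5))
  expect_equal(whole, parts, tolerance = 1e-12)
  # full-range AUC agrees with an independent trapezoid implementation
  expect_equal(melatonin_auc(t, y), pracma::trapz(t, y), tolerance = 1e-12)
})

test_that("closed-form OLS reproduces exact lines and flags degeneracy", {
  f <- fit_dose_response(10^(1:5), 2 * (1:5) + 1)
  expect_equal(unname(coef(f)), c(1, 2))
  expect_equal(f$r, 1)
  # degenerate predictor errors; constant outcome flagged with NA r
  expect_error(fit_dose_response(rep(10, 5), 1:5),
               class = "melanophot_degenerate_error")
  g <- fit_dose_response(10^(1:5), rep(3, 5))
  expect_true(g$degenerate)
  expect_true(is.na(g$r))
  expect_equal(g$slope, 0)
  expect_error(fit_dose_response(1:2, 1:2),
               class = "melanophot_validation_error")
  expect_error(fit_dose_response(c(-1, 1, 2), 1:3),
               class = "melanophot_domain_error")
})

test_that("closed-form fit agrees with lm/cor and keeps OLS identities", {
  set.seed(21)
  for (i in 1:10) {
    dose <- exp(runif(30, 0, 5))
    y <- rnorm(30, 2 - 0.8 * log10(dose), 0.5)
    f <- fit_dose_response(dose, y)
    ref <- lm(y ~ log10(dose))
    expect_equal(unname(coef(f)), unname(coef(ref)), tolerance = 1e-10)
    expect_equal(f$r, cor(log10(dose), y), tolerance = 1e-12)
    expect_equal(f$sigma, summary(ref)$sigma, tolerance = 1e-10)
    # residuals orthogonal to the predictor
    expect_lt(abs(sum(residuals(f) * f$x)), 1e-10 * sd(y) * 30)
    expect_lt(abs(sum(residuals(f))), 1e-10 * 30)
  }
})

test_that("Pearson r is affine-invariant and rescaling shifts intercept only", {
  set.seed(5)
  dose <- exp(runif(40, 0, 4))
  y <- rnorm(40, 1 - 0.5 * log10(dose), 0.3)
  f1 <- fit_dose_response(dose, y)
  f2 <- fit_dose_response(dose * 123.4, y)   # proportional rescale
  expect_equal(f2$r, f1$r, tolerance = 1e-12)
  expect_equal(f2$slope, f1$slope, tolerance = 1e-10)
  expect_equal(f2$intercept, f1$intercept - f1$slope * log10(123.4),
               tolerance = 1e-10)
  f3 <- fit_dose_response(dose, 3 * y + 7)
  expect_equal(abs(f3$r), abs(f1$r), tolerance = 1e-12)
})

test_that("a generated slope of -0.8 mm per decade is recovered at n = 144", {
  set.seed(77)
  dose <- rep(study_conditions()$medi_lx, 18)
  y <- 6.2 - 0.8 * log10(dose) + rnorm(length(dose), 0, 0.35)
  f <- fit_dose_response(dose, y)
  ci <- f$slope + c(-2, 2) * summary(f)$slope_se
  expect_true(ci[1] <= -0.8 && -0.8 <= ci[2])
  expect_lt(f$slope, 0)
})

test_that("predictor comparison is exact under proportional predictors", {
  set.seed(9)
  medi <- rep(study_conditions()$medi_lx, 6)
  auc <- rnorm(length(medi), 40 - 8 * log10(medi), 5)
  cmp <- compare_predictors(auc, medi, 17.3 * medi)  # constant pupil
  expect_equal(cmp$fit_td$r, cmp$fit_medi$r, tolerance = 1e-12)
  expect_equal(cmp$delta_abs_r, 0, tolerance = 1e-12)
  expect_error(compare_predictors(auc, medi, medi[-1]),
               class = "melanophot_validation_error")
})

test_that("fit object methods behave like a standard model object", {
  f <- fit_dose_response(10^(1:4), c(2, 4, 6.1, 7.9))
  expect_equal(predict(f), f$fitted)
  expect_equal(predict(f, newdose = 100), unname(coef(f)[1] + 2 * coef(f)[2]))
  s <- summary(f)
  expect_true(s$p_value >= 0 && s$p_value <= 1)
  expect_output(print(f), "Dose-response fit")
})
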