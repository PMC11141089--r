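# Dose-response layer: melatonin AUC and closed-form log-dose regression,
# including the corneal (mEDI) vs retinal (melanopic troland) predictor
# comparison.

#' Melatonin area under the curve
#'
#' Trapezoidal integral of a melatonin concentration profile over a time
#' window (pg/ml x h). Window endpoints falling between samples are
#' linearly interpolated, which makes the AUC exactly additive over
#' adjacent windows.
#'
#' @param times_h Strictly increasing sampling times (h, e.g. relative to
#'   habitual bedtime).
#' @param conc_pg_ml Concentrations (pg/ml), >= 0.
#' @param window Length-2 integration window; defaults to the full range.
#' @return AUC in pg/ml x h.
#' @examples
#' melatonin_auc(0:3 + 0.0, c(10, 10, 10, 10))        # 30
#' melatonin_auc(c(0, 2), c(0, 10))                   # 10 (triangle)
#' @export
melatonin_auc <- function(times_h, conc_pg_ml, window = range(times_h)) {
  if (length(times_h) != length(conc_pg_ml))
    stop_melanophot("times and concentrations must have equal length",
                    "melanophot_validation_error")
  if (any(diff(times_h) <= 0))
    stop_melanophot("times must be strictly increasing",
                    "melanophot_validation_error")
  if (any(conc_pg_ml < 0))
    stop_melanophot("concentrations must be nonnegative",
                    "melanophot_validation_error")
  lo <- max(window[1L], min(times_h))
  hi <- min(window[2L], max(times_h))
  inside <- times_h > lo & times_h < hi
  if (sum(times_h >= lo & times_h <= hi) < 2L)
    stop_melanophot("need at least 2 samples inside the window",
                    "melanophot_insufficient_data_error")
  tt <- c(lo, times_h[inside], hi)
  cc <- stats::approx(times_h, conc_pg_ml, xout = tt)$y
  sum(diff(tt) * (cc[-1L] + cc[-length(cc)]) / 2)
}

#' Fit a linear dose-response model
#'
#' Ordinary least squares of an outcome against (optionally
#' log10-transformed) dose, computed in closed form together with the
#' Pearson correlation -- the regression behind light dose-response plots
#' of pupil size and melatonin suppression.
#'
#' @param dose Dose values; strictly positive when `log_transform = TRUE`.
#' @param outcome Outcome values, same length, `n >= 3`.
#' @param log_transform Regress on `log10(dose)` (the conventional scale).
#' @param predictor Label for reports, e.g. `"mEDI"` or `"melanopic_Td"`.
#' @return An object of class `"dose_response_fit"` with components
#'   `slope`, `intercept` (outcome units per log10-dose unit when
#'   transformed), `r`, `r2`, `n`, `sigma` (residual SD), `degenerate`
#'   (TRUE when the outcome has zero variance, in which case `r` is `NA`),
#'   `predictor`, and the data (`x`, `y`, `fitted`).
#' @examples
#' f <- fit_dose_response(10^(1:5), 2 * (1:5) + 1)
#' coef(f)            # intercept 1, slope 2
#' f$r                # 1
#' @export
fit_dose_response <- function(dose, outcome, log_transform = TRUE,
                              predictor = "dose") {
  if (length(dose) != length(outcome))
    stop_melanophot("dose and outcome must have equal length",
                    "melanophot_validation_error")
  ok <- is.finite(dose) & is.finite(outcome)
  dose <- dose[ok]; outcome <- outcome[ok]
  n <- length(dose)
  if (n < 3L)
    stop_melanophot("need at least 3 complete observations",
                    "melanophot_validation_error")
  x <- if (log_transform) log10_dose(dose) else dose
  y <- outcome
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  syy <- sum((y - my)^2)
  sxy <- sum((x - mx) * (y - my))
  if (sxx <= 0)
    stop_melanophot("predictor has zero variance (degenerate design)",
                    "melanophot_degenerate_error")
  slope <- sxy / sxx
  intercept <- my - slope * mx
  degenerate <- syy <= 0
  r <- if (degenerate) NA_real_ else sxy / sqrt(sxx * syy)
  fitted <- intercept + slope * x
  rss <- sum((y - fitted)^2)
  structure(list(slope = slope, intercept = intercept,
                 r = r, r2 = if (degenerate) NA_real_ else r * r,
                 n = n, sigma = sqrt(rss / (n - 2L)),
                 degenerate = degenerate,
                 predictor = predictor, log_transform = log_transform,
                 x = x, y = y, fitted = fitted),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Dose-response fit: outcome ~ %s%s\n",
              if (x$log_transform) "log10 " else "", x$predictor))
  cat(sprintf("  slope %.*g  intercept %.*g  R %.3f  n %d\n",
              digits, x$slope, digits, x$intercept, x$r, x$n))
  invisible(x)
}

#' @export
coef.dose_response_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
residuals.dose_response_fit <- function(object, ...) object$y - object$fitted

#' @export
predict.dose_response_fit <- function(object, newdose = NULL, ...) {
  if (is.null(newdose)) return(object$fitted)
  x <- if (object$log_transform) log10_dose(newdose) else newdose
  object$intercept + object$slope * x
}

#' @export
summary.dose_response_fit <- function(object, ...) {
  se <- object$sigma / sqrt(sum((object$x - mean(object$x))^2))
  t <- object$slope / se
  p <- 2 * stats::pt(-abs(t), df = object$n - 2L)
  out <- c(object,
           list(slope_se = se, t_value = t, p_value = p))
  class(out) <- "summary.dose_response_fit"
  out
}

#' @export
print.summary.dose_response_fit <- function(x, ...) {
  print.dose_response_fit(x)
  cat(sprintf("  slope SE %.4g  t %.3f  p %.4g  residual SD %.4g\n",
              x$slope_se, x$t_value, x$p_value, x$sigma))
  invisible(x)
}

#' @export
plot.dose_response_fit <- function(x, ...) {
  graphics::plot(x$x, x$y,
                 xlab = if (x$log_transform)
                   sprintf("log10 %s", x$predictor) else x$predictor,
                 ylab = "outcome", ...)
  graphics::abline(x$intercept, x$slope)
  invisible(x)
}

#' Compare corneal vs retinal dose as predictors
#'
#' Fits the same outcome (typically the melatonin AUC per subject-session)
#' against log10 melanopic EDI and against log10 melanopic trolands, and
#' reports both fits together with the difference in correlation magnitude
#' `delta_abs_r = |r_td| - |r_medi|`. Positive values favour the retinal
#' predictor. Purely descriptive -- no inferential test.
#'
#' @param outcome Outcome per subject-session (e.g. melatonin AUC).
#' @param medi_lx Melanopic EDI per subject-session (lx).
#' @param mel_td Melanopic trolands per subject-session.
#' @return An object of class `"predictor_comparison"`: `fit_medi`,
#'   `fit_td`, `delta_abs_r`.
#' @export
compare_predictors <- function(outcome, medi_lx, mel_td) {
  if (length(outcome) != length(medi_lx) ||
      length(outcome) != length(mel_td))
    stop_melanophot("outcome and both predictors must be aligned",
                    "melanophot_validation_error")
  fit_medi <- fit_dose_response(medi_lx, outcome, predictor = "mEDI")
  fit_td <- fit_dose_response(mel_td, outcome, predictor = "melanopic_Td")
  structure(list(fit_medi = fit_medi, fit_td = fit_td,
                 delta_abs_r = abs(fit_td$r) - abs(fit_medi$r)),
            class = "predictor_comparison")
}

#' @export
print.predictor_comparison <- function(x, ...) {
  cat("Predictor comparison (same outcome):\n")
  cat(sprintf("  mEDI:          R = %.3f\n", x$fit_medi$r))
  cat(sprintf("  melanopic Td:  R = %.3f\n", x$fit_td$r))
  cat(sprintf("  delta |R| (Td - mEDI): %.4f\n", x$delta_abs_r))
  invisible(x)
}
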